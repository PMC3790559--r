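#' Construct an outline object
#'
#' An outline is an ordered, implicitly closed loop of 2-D coordinates for
#' one specimen (the first point is not repeated at the end). `start_index`
#' marks the designated starting landmark, by convention a biologically
#' fixed point such as a curvature maximum on the bone margin.
#'
#' @param points numeric matrix with two columns (x, y) and at least 3 rows.
#' @param specimen_id character scalar.
#' @param start_index index of the starting landmark (default 1).
#' @return an object of class `"outline"`.
#' @export
outline <- function(points, specimen_id = "specimen", start_index = 1L) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  if (nrow(points) < 3L) stop("an outline needs at least 3 points")
  if (!is.numeric(points) || anyNA(points)) stop("`points` must be finite numeric")
  start_index <- as.integer(start_index)
  if (start_index < 1L || start_index > nrow(points)) {
    stop("`start_index` out of range")
  }
  structure(
    list(points = unname(points), specimen_id = as.character(specimen_id),
         start_index = start_index, p = nrow(points), closed = TRUE),
    class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("outline '%s': %d points, start landmark at index %d\n",
              x$specimen_id, x$p, x$start_index))
  invisible(x)
}

#' Read a multi-specimen TPS outline file
#'
#' Parses the TPS dialect written by outline digitizers: one block per
#' specimen starting with `LM=<n>`, followed by `n` rows of `x y`
#' coordinates and optional `ID=`, `IMAGE=` or `SCALE=` lines. When a block
#' has no `ID=` line its 1-based position in the file is used as the id.
#'
#' @param path path to a TPS file.
#' @return list of [outline] objects.
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("TPS file is empty: ", path)
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= blocks found in TPS file: ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L],
                                            ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 1L) {
      stop(sprintf("malformed LM= line in TPS block %d", b))
    }
    body <- block[-1L]
    is_kv <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_kv]
    if (length(coord_lines) != n_lm) {
      stop(sprintf(
        "TPS block %d declares LM=%d but contains %d coordinate rows",
        b, n_lm, length(coord_lines)))
    }
    xy <- t(vapply(strsplit(coord_lines, "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f))
      if (length(v) != 2L || anyNA(v)) {
        stop(sprintf("non-numeric coordinate row in TPS block %d", b))
      }
      v
    }, numeric(2)))
    kv <- body[is_kv]
    id_line <- grep("^ID\\s*=", kv, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line) > 0) {
      sub("^ID\\s*=\\s*", "", id_line[1L], ignore.case = TRUE)
    } else {
      as.character(b)
    }
    out[[b]] <- outline(xy, specimen_id = id)
  }
  out
}

#' Write outlines to a multi-specimen TPS file
#'
#' @param outlines a list of [outline] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(outlines, path) {
  if (inherits(outlines, "outline")) outlines <- list(outlines)
  con <- file(path, "w")
  on.exit(close(con))
  for (o in outlines) {
    stopifnot(inherits(o, "outline"))
    writeLines(sprintf("LM=%d", o$p), con)
    writeLines(sprintf("%.10g %.10g", o$points[, 1L], o$points[, 2L]), con)
    writeLines(sprintf("ID=%s", o$specimen_id), con)
  }
  invisible(path)
}
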