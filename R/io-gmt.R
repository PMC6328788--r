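#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated as name, description,
#' then member gene symbols. Duplicate genes within a set are collapsed;
#' duplicate set names are an error. The minimum-size filter is not
#' applied here (see \code{\link{filterMinSize}}).
#'
#' @param path path to a GMT file (optionally gzipped).
#' @return a \linkS4class{PathwayCollection} with \code{minSize = 0}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(gzfile(path), encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate pathway name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nms
  new("PathwayCollection", pathways = sets, minSize = 0L)
}

#' Write a PathwayCollection as GMT
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "PathwayCollection"))
  pw <- pathways(collection)
  lines <- vapply(names(pw), function(nm)
    paste(c(nm, "na", pw[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Drop gene sets below a minimum size
#'
#' Retains exactly the sets with at least \code{minSize} members.
#' Idempotent; warns when nothing survives.
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param minSize minimum member count (default 10, the usual floor for
#'   pathway-level scoring).
#' @return the filtered \linkS4class{PathwayCollection}.
#' @export
filterMinSize <- function(collection, minSize = 10) {
  stopifnot(is(collection, "PathwayCollection"), minSize >= 1)
  minSize <- as.integer(minSize)
  pw <- pathways(collection)
  keep <- lengths(pw) >= minSize
  if (!any(keep) && length(pw))
    warning("no pathway has >= ", minSize, " genes; empty collection")
  new("PathwayCollection", pathways = pw[keep], minSize = minSize)
}
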