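#' Serialize a dendrogram as Newick
#'
#' Writes an \code{hclust} tree (e.g. from \code{\link{wardD2}}) as a
#' rooted Newick string with branch lengths, where each node sits at
#' its merge height and leaves at height zero, so an edge's length is
#' the height difference between parent and child (for a two-leaf tree
#' merged at height h this is \code{(A:h,B:h);}). Labels containing
#' Newick metacharacters or whitespace are single-quoted.
#'
#' @param tree an object of class \code{hclust}.
#' @param path output path; when \code{NULL} the Newick string is
#'   returned instead of written.
#' @return invisibly, the Newick string.
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  quote_label <- function(x) {
    if (grepl("[][():;,'\\s]", x, perl = TRUE))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  node_str <- function(idx, parent_height) {
    if (idx < 0) {   # leaf
      lab <- quote_label(tree$labels[-idx])
      sprintf("%s:%s", lab, format(parent_height, digits = 12))
    } else {
      h <- tree$height[idx]
      sprintf("(%s,%s):%s",
              node_str(tree$merge[idx, 1L], h),
              node_str(tree$merge[idx, 2L], h),
              format(parent_height - h, digits = 12))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  nwk <- sprintf("(%s,%s);",
                 node_str(tree$merge[root, 1L], h),
                 node_str(tree$merge[root, 2L], h))
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}
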