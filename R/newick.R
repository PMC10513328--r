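# Newick serialization, delegating parsing/formatting to ape with
# package-side structural validation (balanced parentheses reported with
# the character index of the failure).

#' Serialize a tree to Newick
#'
#' Branch lengths are written at `digits` significant digits; bootstrap
#' supports, when present, are written as internal node labels (the
#' dialect FigTree and MEGA read).
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional output path; when NULL the Newick string is
#'   returned only.
#' @param digits Significant digits for branch lengths (default 6).
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  text <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Parse a Newick tree
#'
#' @param x A Newick string or a path to a Newick file.
#' @return An `ape::phylo` tree; internal node labels (bootstrap
#'   supports) are preserved in `node.label`.
#' @export
read_newick <- function(x) {
  text <- if (length(x) == 1 && !grepl("(", x, fixed = TRUE) &&
              file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    abort(sprintf("malformed Newick: unmatched ')' at character %d",
                  which(depth < 0)[1]))
  }
  if (length(depth) > 0 && depth[length(depth)] != 0) {
    abort(sprintf(
      "malformed Newick: %d unclosed '(' at end of input (character %d)",
      depth[length(depth)], length(chars)
    ))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL
  )
  if (is.null(tree)) abort("malformed Newick: ape failed to parse input")
  tree
}
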