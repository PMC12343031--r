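#' Quartet weighting scheme
#'
#' Controls how much each resolved gene-tree quartet contributes to the score.
#'
#' * `"unit"` — every resolved quartet counts 1 (classical quartet score).
#' * `"support"` — a quartet counts the product of the support values of the
#'   internal branches on the path connecting its two pairs in the gene tree;
#'   branches without a support count `default_missing_support`.
#' * `"hybrid"` — the support weight multiplied by `exp(-L)`, where `L` is the
#'   sum of the four terminal-branch path lengths of the induced quartet
#'   subtree (missing lengths contribute 0, so length-free trees get factor 1).
#'
#' Supports are normalized to `[0,1]` at [gene_tree_set()] construction
#' (percent-scale supports are divided by 100).
#'
#' @param mode one of `"unit"`, `"support"`, `"hybrid"`.
#' @param default_missing_support value in `[0,1]` substituted for branches
#'   that carry no support label (default 1).
#' @return an object of class `weight_scheme`.
#' @export
weight_scheme <- function(mode = c("unit", "support", "hybrid"),
                          default_missing_support = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(default_missing_support) || length(default_missing_support) != 1L ||
      is.na(default_missing_support) || default_missing_support < 0 ||
      default_missing_support > 1)
    stop("default_missing_support must be in [0,1]", call. = FALSE)
  structure(list(mode = mode,
                 code = match(mode, c("unit", "support", "hybrid")) - 1L,
                 default_missing_support = default_missing_support),
            class = "weight_scheme")
}

as_weight_scheme <- function(x) {
  if (inherits(x, "weight_scheme")) x else weight_scheme(x)
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight scheme:", x$mode,
      sprintf("(default missing support %.3g)\n", x$default_missing_support))
  invisible(x)
}
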