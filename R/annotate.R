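## Branch annotation: quartet-frequency masses around each internal branch,
## coalescent-unit lengths from the standard multispecies-coalescent
## inversion, and local posterior probabilities by numerical Bayesian
## integration over the branch length.

QS_EPS <- 1e-6
QS_DMAX <- 10

#' Quartet-frequency masses around one internal branch
#'
#' An internal branch of a binary species tree defines a quadripartition
#' (A,B | C,D) of the species set. Over all gene trees and all quadruples
#' with one species from each block, the weight mass is accumulated per
#' pairing: `f1` for the species-tree pairing AB|CD, `f2` for AC|BD, `f3`
#' for AD|BC, each normalized by the total; `n_eff` is the total mass
#' (co-present, resolved quadruples only).
#'
#' @param species_tree binary `phylo`.
#' @param branch index of the internal branch, 1-based in the order internal
#'   branches appear in the unrooted tree's edge matrix (see
#'   [annotate_tree()] for the all-branches loop).
#' @param genes a [gene_tree_set()].
#' @param scheme a [weight_scheme()] or mode string.
#' @return list with `f1`, `f2`, `f3` (NA when `n_eff` is 0), `n_eff`, and
#'   the raw masses `m` (length 3).
#' @export
branch_frequencies <- function(species_tree, branch, genes,
                               scheme = weight_scheme("unit")) {
  scheme <- as_weight_scheme(scheme)
  quad <- species_quadripartitions(unroot_tree(species_tree), genes$species)
  stopifnot(branch >= 1L, branch <= nrow(quad$blocks))
  m <- qs_branch_freq(pp_for_scheme(genes, scheme), quad$blocks[branch, ],
                      scheme$code)
  n_eff <- sum(m)
  if (n_eff > 0)
    list(f1 = m[1] / n_eff, f2 = m[2] / n_eff, f3 = m[3] / n_eff,
         n_eff = n_eff, m = m)
  else
    list(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_, n_eff = 0, m = m)
}

#' Coalescent-unit branch length from the main quartet frequency
#'
#' Under the multispecies coalescent, a quartet around an internal branch of
#' length d (coalescent units) matches the species tree with probability
#' `1 - (2/3) exp(-d)`; inverting gives `d = -log(1.5 (1 - f1))`. Frequencies
#' at or below 1/3 give d = 0; frequencies within `1e-6` of 1 are capped at
#' `Dmax = 10`.
#'
#' @param f1 main quartet frequency in `[0,1]` (NA allowed, giving NA).
#' @param n_eff effective observation count (unused beyond a 0-guard).
#' @return branch length in coalescent units.
#' @export
coalescent_length <- function(f1, n_eff = Inf) {
  if (is.na(f1)) return(NA_real_)
  if (!is.numeric(f1) || f1 < 0 || f1 > 1)
    stop("f1 must be in [0,1]", call. = FALSE)
  if (isTRUE(n_eff == 0)) return(NA_real_)
  if (f1 <= 1 / 3) return(0)
  if (f1 >= 1 - QS_EPS) return(QS_DMAX)
  -log(1.5 * (1 - f1))
}

## log integrand grid shared by local_pp
pp_grid <- function(n = 201L, lo = 1e-6, hi = 20) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Local posterior probability of a branch
#'
#' Posterior probability that pairing 1 is the species-tree pairing given the
#' three observed quartet-frequency masses, under a uniform 1/3 prior over
#' the pairings, an exponential(1) prior on the branch length d, and the
#' multispecies-coalescent per-observation probabilities
#' `(1 - (2/3)e^{-d}, (1/3)e^{-d}, (1/3)e^{-d})`. The d-integral is computed
#' on a fixed 201-point log-spaced grid on `[1e-6, 20]` by the trapezoid
#' rule, in log space for numerical stability.
#'
#' @param m1,m2,m3 non-negative masses (weighted quartet counts), not all 0.
#' @param grid_n integration grid size (201 default; used by tests to check
#'   grid convergence).
#' @return probability in `[0,1]`; `NA` for all-zero masses.
#' @export
local_pp <- function(m1, m2, m3, grid_n = 201L) {
  m <- c(m1, m2, m3)
  if (any(is.na(m))) return(NA_real_)
  if (any(m < 0)) stop("masses must be non-negative", call. = FALSE)
  if (sum(m) == 0) return(NA_real_)
  d <- pp_grid(grid_n)
  log_p_match <- log1p(-(2 / 3) * exp(-d))
  log_p_mis <- log(1 / 3) - d
  ## log marginal likelihood of topology t: integral over d of
  ## exp(-d) * p_match^m_t * p_mis^(m_u + m_v)
  logI <- vapply(1:3, function(t) {
    li <- -d + m[t] * log_p_match + (sum(m) - m[t]) * log_p_mis
    mx <- max(li)
    mx + log(trapz(d, exp(li - mx)))
  }, numeric(1))
  mx <- max(logI)
  w <- exp(logI - mx)
  w[1] / sum(w)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Annotate every internal branch of a species tree
#'
#' Computes quartet-frequency masses, local posterior probability and
#' coalescent-unit length for each internal branch, serializing them as
#' internal-node labels `q1=..;q2=..;q3=..;pp=..;n=..` (quoted on Newick
#' output since `;` is a metacharacter) with the coalescent length as the
#' branch length. `label_mode = "pp"` or `"support"` emit a single scalar
#' (posterior probability or `q1`) for strict-Newick consumers.
#'
#' @param species_tree binary `phylo`.
#' @param genes a [gene_tree_set()].
#' @param scheme a [weight_scheme()] or mode string.
#' @param label_mode `"full"`, `"pp"` or `"support"`.
#' @return the species tree (unrooted) with node labels and branch lengths
#'   replaced by annotations; terminal branch lengths are set missing.
#' @export
annotate_tree <- function(species_tree, genes, scheme = weight_scheme("unit"),
                          label_mode = c("full", "pp", "support")) {
  label_mode <- match.arg(label_mode)
  scheme <- as_weight_scheme(scheme)
  tree <- unroot_tree(species_tree)
  quad <- species_quadripartitions(tree, genes$species)
  tree <- quad$tree
  n <- n_tips(tree)
  tree$node.label <- rep("", tree$Nnode)
  tree$edge.length <- rep(NA_real_, nrow(tree$edge))
  pp_set <- pp_for_scheme(genes, scheme)
  for (i in seq_len(nrow(quad$blocks))) {
    m <- qs_branch_freq(pp_set, quad$blocks[i, ], scheme$code)
    n_eff <- sum(m)
    if (n_eff > 0) {
      f <- m / n_eff
      pp <- local_pp(m[1], m[2], m[3])
      d <- coalescent_length(f[1], n_eff)
    } else {
      f <- rep(NA_real_, 3); pp <- NA_real_; d <- NA_real_
    }
    lab <- switch(label_mode,
                  full = sprintf("q1=%s;q2=%s;q3=%s;pp=%s;n=%s",
                                 fmt4(f[1]), fmt4(f[2]), fmt4(f[3]),
                                 fmt4(pp), fmt4(n_eff)),
                  pp = fmt4(pp),
                  support = fmt4(f[1]))
    tree$node.label[quad$child[i] - n] <- lab
    tree$edge.length[quad$rows[i]] <- d
  }
  tree
}

fmt4 <- function(x) {
  if (is.na(x)) "NA" else format(round(x, 4), trim = TRUE, scientific = FALSE)
}
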