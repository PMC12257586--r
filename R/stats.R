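#' @title Population statistics for PARCH tables
#' @name parch_stats
#' @description
#' Dataset-level analysis of PARCH values: probability densities of BB and
#' NB scores, per-nucleotide-type summaries, the Kruskal-Wallis omnibus test
#' across residue types with a Dunn post hoc, and complex-versus-component
#' score deltas stratified by interface contact.
NULL

#' Probability density of PARCH values
#'
#' Normalized histogram density (Freedman-Diaconis bins by default) or, with
#' `kernel = TRUE`, a Gaussian kernel density renormalized to unit area over
#' its support. Constant input with the kernel estimator falls back to a
#' point mass with a warning.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param bins histogram break specification (passed to [hist()]); ignored
#'   for the kernel estimator.
#' @param kernel use `stats::density()` instead of a histogram.
#' @param bw kernel bandwidth (default `"nrd0"`).
#' @return a `parch_density`: list with `x` (support grid), `density`,
#'   `width` (bin width or bandwidth), `mode`.
#' @export
parch_density <- function(values, bins = "FD", kernel = FALSE, bw = "nrd0") {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop_validation("need at least 2 finite values")
  if (diff(range(values)) == 0) {
    if (kernel)
      warn_parch("constant input: kernel estimator degenerates to a point mass")
    # unit-area point mass: one narrow bin centered on the value
    w <- 1e-6
    return(structure(list(x = values[1L], density = 1 / w, width = w,
                          mode = values[1L]), class = "parch_density"))
  }
  if (kernel) {
    d <- stats::density(values, bw = bw)
    area <- sum((d$y[-1L] + d$y[-length(d$y)]) / 2 * diff(d$x))
    out <- list(x = d$x, density = d$y / area, width = d$bw)
  } else {
    h <- graphics::hist(values, breaks = bins, plot = FALSE)
    out <- list(x = h$mids, density = h$density,
                width = diff(h$breaks)[1L])
  }
  out$mode <- out$x[which.max(out$density)]
  structure(out, class = "parch_density")
}

#' Per-type summary of a PARCH table
#'
#' Mean, sd, mode (from the density estimator), min, max and count of PV for
#' every residue type x region combination — the per-nucleotide reporting
#' unit of the scale (e.g. the dataset average backbone score of dA). sd and
#' mode are `NA` for singleton groups.
#'
#' @param table a `parch_table`.
#' @param ... passed to [parch_density()] for the mode estimate.
#' @return data frame with columns `resname`, `alpha`, `mean`, `sd`, `mode`,
#'   `min`, `max`, `n`.
#' @export
per_type_summary <- function(table, ...) {
  if (!nrow(table)) stop_validation("empty parch_table")
  key <- paste(table$resname, table$alpha, sep = "\r")
  rows <- lapply(split(table$PV, factor(key, levels = unique(key))),
                 function(v) {
    data.frame(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               mode = if (length(v) > 1L) parch_density(v, ...)$mode else v[1L],
               min = min(v), max = max(v), n = length(v))
  })
  ids <- strsplit(names(rows), "\r", fixed = TRUE)
  out <- cbind(data.frame(resname = vapply(ids, `[[`, "", 1L),
                          alpha = vapply(ids, `[[`, "", 2L),
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}


#' Kruskal-Wallis comparison of PARCH value groups
#'
#' Rank-based omnibus test (tie-corrected H) across k groups — e.g. backbone
#' PV lists of the four nucleotide types. The p-value comes from the
#' chi-square approximation with k - 1 degrees of freedom
#' (`stats::kruskal.test`), or from a seeded Monte-Carlo permutation null
#' with `method = "permutation"`. An optional Dunn post hoc with Holm
#' correction localizes pairwise differences.
#'
#' @param groups named list of numeric vectors (>= 2 groups, every group
#'   nonempty, total n >= 3).
#' @param method `"chisq"` or `"permutation"`.
#' @param n_perm number of permutation draws.
#' @param seed seed for the permutation draws.
#' @param posthoc also run [dunn_posthoc()].
#' @return list with `H`, `df`, `p`, `method`, and optionally `posthoc`.
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "permutation"),
                           n_perm = 1e5, seed = 1L, posthoc = FALSE) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop_validation("need a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0L))
    stop_validation("every group must be nonempty")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop_validation("need total n >= 3")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  h_obs <- unname(kt$statistic)
  df <- unname(kt$parameter)
  if (method == "chisq") {
    p <- kt$p.value
  } else {
    # the pooled ranks and the tie correction are invariant under
    # relabeling, so the permutation null is a pure rank-sum reshuffle
    ranks <- rank(values)
    sizes <- lengths(groups)
    n <- length(ranks)
    ties <- table(ranks)
    tiecorr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (tiecorr <= 0) {
      p <- 1  # every pooled value identical: H is 0 under any labeling
    } else {
      ind <- stats::model.matrix(~ g - 1)
      h_perm <- with_seed(seed, {
        perm_ranks <- replicate(n_perm, sample(ranks))
        sums <- t(ind) %*% perm_ranks  # k x n_perm rank sums
        h <- 12 / (n * (n + 1)) * colSums(sums^2 / sizes) - 3 * (n + 1)
        h / tiecorr
      })
      p <- (1 + sum(h_perm >= h_obs - 1e-12)) / (n_perm + 1)
    }
  }
  out <- list(H = h_obs, df = df, p = p, method = method)
  if (posthoc) out$posthoc <- dunn_posthoc(groups)
  out
}

#' Dunn pairwise post hoc after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the standard tie correction;
#' two-sided p-values, Holm-adjusted by default (Holm never rejects more
#' than the unadjusted tests).
#'
#' @param groups named list of numeric vectors.
#' @param p_adjust adjustment method for [stats::p.adjust()].
#' @return data frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, p_adjust = "holm") {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(values)
  n <- length(values)
  rbar <- tapply(r, g, mean)[names(groups)]
  sizes <- lengths(groups)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[pr[1L]]] + 1 / sizes[[pr[2L]]]))
    (rbar[[pr[1L]]] - rbar[[pr[2L]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Interface contact regions of a complex
#'
#' Regions of a complex whose atoms approach the partner molecule: a region
#' is a contact if any of its atoms lies within `cutoff` of any atom of the
#' partner selection (default 4.5 A).
#'
#' @param system a `parch_system` of the complex.
#' @param partner_chains chain identifiers of the partner molecule; regions
#'   on these chains are not themselves reported.
#' @param cutoff contact distance, Angstrom.
#' @return character vector of region ids (see [region_id()]).
#' @export
contact_regions <- function(system, partner_chains, cutoff = 4.5) {
  atoms <- system$atoms
  part <- which(atoms$role == "solute" & atoms$chain %in% partner_chains)
  if (!length(part)) stop_validation("partner selection is empty")
  pxyz <- as.matrix(atoms[part, c("x", "y", "z")])
  ids <- character()
  for (r in system$regions) {
    if (r$chain %in% partner_chains) next
    rxyz <- as.matrix(atoms[r$atom_idx, c("x", "y", "z"), drop = FALSE])
    if (min(min_dist2(rxyz, pxyz)) <= cutoff^2) ids <- c(ids, region_id(r))
  }
  ids
}

#' Complex-versus-component PARCH deltas
#'
#' Matches regions between the PARCH table of a complex and of an isolated
#' component and reports `delta = PV_component - PV_complex` per region
#' (positive: the residue is more hydrophilic when free, i.e. binding
#' lowered its hydropathy). With a contact list the deltas are additionally
#' summarized for contact versus non-contact regions. Regions present in
#' only one table are dropped with a logged count.
#'
#' @param table_complex,table_component `parch_table`s sharing residue keys.
#' @param contacts optional character vector of contact region ids (see
#'   [contact_regions()]).
#' @return list with `deltas` (per-region data frame), `summary` (stratified
#'   means, if contacts given), `n_unmatched`.
#' @export
complex_delta <- function(table_complex, table_component, contacts = NULL) {
  id <- function(t) paste(t$chain, t$resseq, t$resname, t$alpha, sep = ":")
  ia <- id(table_complex); ib <- id(table_component)
  shared <- intersect(ia, ib)
  if (!length(shared)) stop_validation("no shared residue keys between tables")
  n_unmatched <- (length(ia) - length(shared)) + (length(ib) - length(shared))
  if (n_unmatched > 0L)
    message(n_unmatched, " region(s) present in only one table; excluded")
  a <- table_complex[match(shared, ia), , drop = FALSE]
  b <- table_component[match(shared, ib), , drop = FALSE]
  deltas <- data.frame(region = shared, chain = a$chain, resseq = a$resseq,
                       resname = a$resname, alpha = a$alpha,
                       PV_complex = a$PV, PV_component = b$PV,
                       delta = b$PV - a$PV, stringsAsFactors = FALSE)
  out <- list(deltas = deltas, n_unmatched = n_unmatched)
  if (!is.null(contacts)) {
    deltas$contact <- deltas$region %in% contacts
    out$deltas <- deltas
    out$summary <- do.call(rbind, lapply(split(deltas, deltas$contact),
                                         function(d) data.frame(
      contact = d$contact[1L], mean_delta = mean(d$delta),
      sd_delta = if (nrow(d) > 1L) stats::sd(d$delta) else NA_real_,
      n = nrow(d))))
    rownames(out$summary) <- NULL
  }
  out
}
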