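# Screen-quality metrics: Z-factor, Welch t-test on control separation,
# cross-assay Pearson correlation, and combination-treatment excess
# inhibition.

#' Z-factor (screening-window coefficient)
#'
#' \deqn{Z = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' computed from the positive- and negative-control readings of an assay.
#' Z is at most 1; values near 1 indicate well-separated controls, values
#' below 0 an unusable assay window. SDs use the n-1 denominator.
#'
#' @param positive_values numeric readings of the positive control.
#' @param negative_values numeric readings of the negative control.
#' @return the Z-factor, a single number <= 1.
#' @export
z_factor <- function(positive_values, negative_values) {
  if (length(positive_values) < 2L || length(negative_values) < 2L)
    stop_validation("need >= 2 values per control group")
  mu_p <- mean(positive_values); mu_n <- mean(negative_values)
  if (mu_p == mu_n)
    stop_validation("Z-factor undefined: control means are equal")
  1 - 3 * (stats::sd(positive_values) + stats::sd(negative_values)) /
    abs(mu_p - mu_n)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' two-tailed; used to compare siRNA control groups.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`, and per-group means/SDs/sizes.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_validation("need >= 2 values per group")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b))
    stop_validation("degenerate test: zero variance and equal means")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b),
       sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
       n_a = length(group_a), n_b = length(group_b))
}

#' Pairwise correlation of assay endpoints across siRNAs
#'
#' Pearson correlation between every pair of assays over the experimental
#' siRNA fold changes, matched on (gene, siRNA) and computed separately for
#' the requested condition. Pairs are intersected listwise per assay pair;
#' control wells never enter.
#'
#' @param agg per-siRNA fold changes ([aggregate_sirna()] output).
#' @param condition `"treated"` or `"vehicle"`.
#' @param assays assays to correlate (default: those present).
#' @return list with `r` (symmetric correlation matrix, unit diagonal) and
#'   `n` (matrix of pairwise siRNA counts).
#' @export
cross_screen_correlation <- function(agg, condition = "treated",
                                     assays = NULL) {
  sub <- agg[agg$condition == condition, , drop = FALSE]
  if (is.null(assays)) assays <- sort(unique(sub$assay))
  wide <- lapply(assays, function(a) {
    s <- sub[sub$assay == a, , drop = FALSE]
    stats::setNames(s$fold_change,
                    paste(s$screen_batch, s$gene_id, s$sirna_id, sep = "\r"))
  })
  names(wide) <- assays
  p <- length(assays)
  r <- diag(1, p); dimnames(r) <- list(assays, assays)
  n <- matrix(0L, p, p, dimnames = list(assays, assays))
  diag(n) <- vapply(wide, length, integer(1))
  if (p > 1) for (i in 1:(p - 1)) for (j in (i + 1):p) {
    shared <- intersect(names(wide[[i]]), names(wide[[j]]))
    if (length(shared) < 3L)
      stop_validation(sprintf("fewer than 3 shared siRNAs between %s and %s",
                              assays[i], assays[j]))
    x <- wide[[i]][shared]; y <- wide[[j]][shared]
    if (stats::sd(x) == 0)
      stop_validation(paste("zero-variance fold changes in assay", assays[i]))
    if (stats::sd(y) == 0)
      stop_validation(paste("zero-variance fold changes in assay", assays[j]))
    r[i, j] <- r[j, i] <- stats::cor(x, y)
    n[i, j] <- n[j, i] <- length(shared)
  }
  list(r = r, n = n, condition = condition)
}

#' Excess inhibition of a combination treatment
#'
#' Percent inhibition is I = 100 - viability%, per treatment arm. The excess
#' of the combination over additivity is E = I_combo - (I_A + I_B), computed
#' per matched replicate experiment, with a paired two-tailed t-test of
#' I_combo against I_A + I_B across replicates (requires >= 2 replicates and
#' a non-constant difference; otherwise `p` is `NA`).
#'
#' @param viability_a,viability_b,viability_combo viability percentages
#'   (0-100 scale) for arm A alone, arm B alone and the combination, matched
#'   by replicate.
#' @return list with per-replicate inhibitions `I_a`, `I_b`, `I_combo`,
#'   excess vector `E`, `mean_E`, and paired-test `t`/`p`.
#' @export
combination_excess <- function(viability_a, viability_b, viability_combo) {
  n <- length(viability_combo)
  if (length(viability_a) != n || length(viability_b) != n)
    stop_validation("treatment arms must have matched replicate counts")
  i_a <- 100 - viability_a
  i_b <- 100 - viability_b
  i_combo <- 100 - viability_combo
  e <- i_combo - (i_a + i_b)
  t_stat <- p <- NA_real_
  if (n >= 2L && stats::sd(e) > 0) {
    ht <- stats::t.test(i_combo, i_a + i_b, paired = TRUE)
    t_stat <- unname(ht$statistic); p <- ht$p.value
  }
  list(I_a = i_a, I_b = i_b, I_combo = i_combo, E = e,
       mean_E = mean(e), t = t_stat, p = p)
}

#' Quality-control report for a screen
#'
#' Per batch x assay: the Z-factor of the siCelldeath (or other positive
#' control) vs siNeg separation in the treated condition, a Welch t-test of
#' the same separation, and per-plate siNeg treated means as a drift check.
#'
#' @param measurements normalized well records.
#' @param positive_role control role providing the positive signal window
#'   (default `"siCelldeath"` for viability; `"siFLIP"` is typical for the
#'   caspase assays).
#' @param condition condition assessed (default `"treated"`).
#' @return nested list keyed by batch then assay with `z_factor`, `welch`
#'   and `plate_sineg_means`.
#' @export
qc_report <- function(measurements, positive_role = "siCelldeath",
                      condition = "treated") {
  if (!"fold_change" %in% names(measurements))
    stop_validation("measurements must be normalized first")
  out <- list()
  for (batch in sort(unique(measurements$screen_batch))) {
    b <- measurements[measurements$screen_batch == batch &
                        measurements$condition == condition, , drop = FALSE]
    out[[batch]] <- list()
    for (assay in sort(unique(b$assay))) {
      ba <- b[b$assay == assay, , drop = FALSE]
      pos <- ba$fold_change[ba$sample_role == positive_role]
      neg <- ba$fold_change[ba$sample_role == "siNeg"]
      entry <- list(n_pos = length(pos), n_neg = length(neg))
      if (length(pos) >= 2L && length(neg) >= 2L &&
          mean(pos) != mean(neg)) {
        entry$z_factor <- z_factor(pos, neg)
        entry$welch <- welch_t_test(pos, neg)
      }
      sineg <- ba[ba$sample_role == "siNeg", , drop = FALSE]
      entry$plate_sineg_means <-
        tapply(sineg$fold_change, sineg$plate_id, mean)
      out[[batch]][[assay]] <- entry
    }
  }
  out
}
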