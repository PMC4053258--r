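# Control-derived SD thresholds and the m-of-n siRNA redundancy hit-calling
# rule, with two stringency tiers, cross-assay corroboration, median ranking
# and the secondary-screen summary matrix.

TIER_LEVELS <- c(high = "+", low = "(+)", none = "-")

#' Control statistics and SD thresholds for one batch x assay x condition
#'
#' Pools the normalized fold changes of all siNeg wells of a screen batch
#' under the requested condition (across plates), and derives the
#' k-standard-deviation hit thresholds
#' \eqn{T_{up}(k) = \mu + k\sigma}, \eqn{T_{down}(k) = \mu - k\sigma}
#' for k in 1, 2. The sample standard deviation (n-1 denominator) is used.
#'
#' @param measurements normalized well records.
#' @param batch screen batch identifier.
#' @param assay one of `"caspase8"`, `"caspase3_7"`, `"viability"`.
#' @param condition `"treated"` (default) or `"vehicle"`.
#' @param role control role defining the null distribution (default
#'   `"siNeg"`).
#' @return object of class `control_stats`: list with `screen_batch`,
#'   `assay`, `condition`, `n`, `mu`, `sigma`, `t_up` and `t_down` (named
#'   vectors for k1, k2).
#' @export
compute_control_stats <- function(measurements, batch, assay,
                                  condition = "treated", role = "siNeg") {
  if (!"fold_change" %in% names(measurements))
    stop_validation("measurements must be normalized first")
  sel <- measurements$screen_batch == batch &
    measurements$assay == assay &
    measurements$condition == condition &
    measurements$sample_role == role
  f <- measurements$fold_change[sel]
  if (length(f) < 2L)
    stop_validation(sprintf(
      "need >= 2 %s wells for batch '%s', assay '%s', condition '%s' (found %d)",
      role, batch, assay, condition, length(f)))
  mu <- mean(f)
  sigma <- stats::sd(f)
  k <- c(k1 = 1, k2 = 2)
  structure(list(screen_batch = batch, assay = assay, condition = condition,
                 n = length(f), mu = mu, sigma = sigma,
                 t_up = mu + k * sigma, t_down = mu - k * sigma),
            class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat(sprintf("control stats [%s / %s / %s]: n=%d mu=%.4g sigma=%.4g\n",
              x$screen_batch, x$assay, x$condition, x$n, x$mu, x$sigma))
  cat(sprintf("  T_up(1)=%.4g T_up(2)=%.4g T_down(1)=%.4g T_down(2)=%.4g\n",
              x$t_up["k1"], x$t_up["k2"], x$t_down["k1"], x$t_down["k2"]))
  invisible(x)
}

#' Flag siRNAs against SD thresholds
#'
#' Marks each per-siRNA fold change that lies strictly beyond the control
#' thresholds: `flag_up_k` is `F > T_up(k)` and `flag_down_k` is
#' `F < T_down(k)`. Values exactly on a threshold do not qualify.
#'
#' @param records per-siRNA fold changes (output of [aggregate_sirna()]),
#'   already restricted to one batch/assay/condition or carrying those
#'   columns matching `stats`.
#' @param stats a `control_stats` object for the same batch, assay and
#'   condition.
#' @return `records` with logical columns flag_up_k1, flag_up_k2,
#'   flag_down_k1, flag_down_k2.
#' @export
flag_sirnas <- function(records, stats) {
  stopifnot(inherits(stats, "control_stats"))
  for (col in c("screen_batch", "assay", "condition")) {
    if (col %in% names(records)) {
      mismatch <- records[[col]] != stats[[sub("screen_batch", "screen_batch",
                                               col)]]
      if (any(mismatch))
        stop_validation(sprintf(
          "records %s does not match control stats (%s vs %s)", col,
          records[[col]][which(mismatch)[1L]], stats[[col]]))
    }
  }
  f <- records$fold_change
  records$flag_up_k1 <- f > stats$t_up[["k1"]]
  records$flag_up_k2 <- f > stats$t_up[["k2"]]
  records$flag_down_k1 <- f < stats$t_down[["k1"]]
  records$flag_down_k2 <- f < stats$t_down[["k2"]]
  records
}

#' Gene-level call from flagged siRNAs (m-of-n redundancy rule)
#'
#' A gene is called at high stringency ("+") when at least `m` of its siRNAs
#' are flagged at 2 SD in the requested direction, at low stringency ("(+)")
#' when at least `m` are flagged at 1 SD but the 2-SD count falls short, and
#' "-" otherwise. Requiring several independent reagents guards against
#' single-siRNA off-target effects. Genes with fewer than `m` usable siRNAs
#' are reported as uncallable rather than dropped.
#'
#' @param flags flagged siRNA records for a single gene x assay.
#' @param m minimum number of qualifying siRNAs (default 3).
#' @param direction `"up"` (signal increase) or `"down"` (decrease).
#' @return one-row data.frame: gene_id, assay, direction, n, n_k1, n_k2,
#'   tier, callable.
#' @export
call_gene <- function(flags, m = 3L, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!nrow(flags)) stop_validation("empty flag set")
  if (length(unique(flags$gene_id)) != 1L)
    stop_validation("flags must come from a single gene")
  k1 <- flags[[paste0("flag_", direction, "_k1")]]
  k2 <- flags[[paste0("flag_", direction, "_k2")]]
  n <- nrow(flags)
  n_k1 <- sum(k1)
  n_k2 <- sum(k2)
  callable <- n >= m
  tier <- if (!callable) "none"
  else if (n_k2 >= m) "high"
  else if (n_k1 >= m) "low"
  else "none"
  data.frame(gene_id = flags$gene_id[1L], assay = flags$assay[1L],
             direction = direction, n = n, n_k1 = n_k1, n_k2 = n_k2,
             tier = TIER_LEVELS[[tier]], callable = callable,
             stringsAsFactors = FALSE)
}

#' Call every gene of a screen
#'
#' Runs the full hit-calling path for one assay and direction: per-batch
#' control statistics from pooled siNeg wells under the treated condition,
#' per-siRNA flagging, and the m-of-n gene rule. Screen batches are analyzed
#' independently, each against its own thresholds. Genes absent from the
#' annotation are still called, with gene_set `"unknown"`, and reported via
#' a warning.
#'
#' @param measurements normalized well records (all roles retained).
#' @param annotation gene-set annotation (gene_id, gene_set); `NULL` labels
#'   every gene `"unknown"` silently.
#' @param assay assay to call on.
#' @param direction `"up"` or `"down"` relative to the siNeg null.
#' @param m minimum qualifying siRNAs (default 3).
#' @param condition condition the thresholds and fold changes refer to
#'   (default `"treated"`).
#' @return data.frame of gene calls with gene_set and screen_batch columns;
#'   attribute `"control_stats"` holds the per-batch `control_stats` objects.
#' @export
call_screen <- function(measurements, annotation = NULL, assay,
                        direction = c("up", "down"), m = 3L,
                        condition = "treated") {
  direction <- match.arg(direction)
  agg <- aggregate_sirna(measurements)
  agg <- agg[agg$assay == assay & agg$condition == condition, , drop = FALSE]
  if (!nrow(agg)) stop_validation(sprintf(
    "no experimental measurements for assay '%s', condition '%s'",
    assay, condition))

  stats_by_batch <- list()
  calls <- list()
  for (batch in sort(unique(agg$screen_batch))) {
    cs <- compute_control_stats(measurements, batch, assay, condition)
    stats_by_batch[[batch]] <- cs
    sub <- flag_sirnas(agg[agg$screen_batch == batch, , drop = FALSE], cs)
    per_gene <- lapply(split(sub, sub$gene_id), call_gene,
                       m = m, direction = direction)
    batch_calls <- do.call(rbind, per_gene)
    batch_calls$screen_batch <- batch
    calls[[batch]] <- batch_calls
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  if (is.null(annotation)) {
    calls$gene_set <- "unknown"
  } else {
    annotation <- validate_annotation(annotation)
    idx <- match(calls$gene_id, annotation$gene_id)
    calls$gene_set <- ifelse(is.na(idx), "unknown",
                             annotation$gene_set[idx])
    unknown <- calls$gene_id[is.na(idx)]
    if (length(unknown))
      warning("genes not in annotation (called with gene_set 'unknown'): ",
              paste(sort(unique(unknown)), collapse = ", "))
  }
  calls <- calls[order(calls$screen_batch, calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "control_stats") <- stats_by_batch
  calls
}

#' Count called genes by tier and gene set
#'
#' @param calls output of [call_screen()].
#' @return data.frame of counts of "+" and "(+)" calls per gene set.
#' @export
tally_calls <- function(calls) {
  out <- stats::aggregate(
    cbind(n_high = tier == "+", n_low = tier == "(+)",
          n_called = tier != "-") ~ gene_set,
    data = calls, FUN = sum)
  out$n_genes <- as.vector(table(calls$gene_set)[out$gene_set])
  out
}

#' Corroborate primary calls with the companion assays
#'
#' The primary verdict (caspase-3/7 increase under treatment) is checked
#' against the two companion endpoints: a viability decrease (fold change
#' below the siNeg-derived lower threshold; 2-SD tier reported with the 1-SD
#' tier as fallback) and a caspase-8 increase, evaluated at the relaxed 1-SD
#' stringency. `n_assays_supporting` counts companion assays with a
#' qualifying tier: viability at 2 SD, caspase-8 at 1 SD.
#'
#' @param primary_calls caspase-3/7 "up" calls from [call_screen()].
#' @param viability_calls viability "down" calls (may be `NULL`).
#' @param caspase8_calls caspase-8 "up" calls (may be `NULL`).
#' @return data.frame keyed by gene_id with primary_tier, viability_tier,
#'   caspase8_tier, n_assays_supporting and a `complete` flag for genes
#'   covered by all three assays.
#' @export
corroborate_calls <- function(primary_calls, viability_calls = NULL,
                              caspase8_calls = NULL) {
  tier_of <- function(calls, gene) {
    if (is.null(calls)) return(NA_character_)
    i <- match(gene, calls$gene_id)
    if (is.na(i)) NA_character_ else calls$tier[i]
  }
  k1_count <- function(calls, gene) {
    if (is.null(calls)) return(NA_integer_)
    i <- match(gene, calls$gene_id)
    if (is.na(i)) NA_integer_ else calls$n_k1[i]
  }
  genes <- primary_calls$gene_id
  viab <- vapply(genes, tier_of, character(1), calls = viability_calls)
  c8 <- vapply(genes, tier_of, character(1), calls = caspase8_calls)
  c8_k1 <- vapply(genes, k1_count, integer(1), calls = caspase8_calls)
  m_used <- 3L
  # caspase-8 corroborates at the relaxed 1-SD stringency: >= m siRNAs past
  # T_up(1), i.e. tier "+" or "(+)" both qualify
  c8_support <- !is.na(c8_k1) & c8_k1 >= m_used
  viab_support_high <- !is.na(viab) & viab == "+"
  data.frame(
    gene_id = genes,
    primary_tier = primary_calls$tier,
    viability_tier = viab,
    caspase8_tier = c8,
    viability_supports = viab_support_high,
    viability_supports_relaxed = !is.na(viab) & viab %in% c("+", "(+)"),
    caspase8_supports = c8_support,
    n_assays_supporting = as.integer(viab_support_high) +
      as.integer(c8_support),
    complete = !is.na(viab) & !is.na(c8),
    stringsAsFactors = FALSE)
}

#' Rank genes by the median fold change of their siRNAs
#'
#' Orders genes by descending median treated-condition fold change over each
#' gene's siRNAs (for four reagents, the mean of the middle pair). Ties are
#' broken lexicographically by gene identifier so the ranking is
#' deterministic.
#'
#' @param agg per-siRNA fold changes ([aggregate_sirna()] output).
#' @param assay assay to rank on.
#' @param condition condition (default `"treated"`).
#' @return data.frame gene_id, median_fold_change, rank (1 = largest).
#' @export
rank_by_median <- function(agg, assay, condition = "treated") {
  sub <- agg[agg$assay == assay & agg$condition == condition, , drop = FALSE]
  if (!nrow(sub)) stop_validation("no measurements to rank")
  med <- tapply(sub$fold_change, sub$gene_id, stats::median)
  out <- data.frame(gene_id = names(med),
                    median_fold_change = as.numeric(med),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$median_fold_change, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Secondary-screen summary matrix
#'
#' Builds the genes x cell-lines tier matrix of a validation screen: each
#' cell line's dataset is called against its own siNeg controls, and the
#' resulting tier symbol ("+", "(+)", "-") is tabulated per gene. Genes
#' missing from a cell line are `NA`, not "-".
#'
#' @param datasets named list of normalized well-record tables, one per cell
#'   line (names become columns).
#' @param genes optional gene panel ordering the rows; defaults to the union
#'   of genes seen, sorted.
#' @param assay assay to call on (default `"caspase3_7"`).
#' @param direction call direction (default `"up"`).
#' @param m minimum qualifying siRNAs (default 3).
#' @return character matrix of tier symbols with attribute
#'   `"n_high_per_line"`, the count of "+" calls per cell line.
#' @export
secondary_matrix <- function(datasets, genes = NULL, assay = "caspase3_7",
                             direction = "up", m = 3L) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  calls <- lapply(datasets, call_screen, annotation = NULL, assay = assay,
                  direction = direction, m = m)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(calls, `[[`, "gene_id"))))
  mat <- matrix(NA_character_, nrow = length(genes), ncol = length(calls),
                dimnames = list(genes, names(calls)))
  for (line in names(calls)) {
    idx <- match(genes, calls[[line]]$gene_id)
    mat[, line] <- calls[[line]]$tier[idx]
  }
  attr(mat, "n_high_per_line") <- colSums(mat == "+", na.rm = TRUE)
  mat
}
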