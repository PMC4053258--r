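# Synthetic arrayed-screen generator: 384-well plates, four siRNAs per gene,
# control wells, paired vehicle/treated conditions, three luminescence
# endpoints with a configurable cross-endpoint effect correlation, planted
# negative/positive regulators with per-siRNA efficacy heterogeneity, and
# recovery metrics against the planted truth.

#' Configuration for a simulated screen
#'
#' Defaults emulate a two-batch primary screen: a kinome-plus-additional
#' batch (691 + 238 genes, three endpoints) and a phosphatase batch
#' (206 genes, caspase-3/7 and viability only), four siRNAs per gene on
#' 384-well plates with 24 control wells each. Baseline treated/vehicle
#' signal ratios are 6.5 for caspase-3/7, 2.25 for caspase-8 and 0.5 for
#' viability, matching a ligand dose that activates executioner caspases
#' six- to sevenfold, initiator caspase two- to 2.5-fold, and halves
#' viability in control cells. Well noise is multiplicative log-normal
#' (sdlog 0.28); plates carry a log-normal scale factor (sdlog 0.1).
#' About 13% of genes are planted negative regulators and 1% positive
#' regulators; effect strengths for the caspase and viability endpoints of
#' a gene share a latent correlation `rho` (default 0.7). Each siRNA draws
#' an efficacy from Beta(5, 1.5) and fails outright (efficacy 0) with
#' probability `p_fail` (default 0.25), the failure mode that motivates the
#' 3-of-4 redundancy rule.
#'
#' @param n_genes named integer vector: genes per gene set.
#' @param batches named list; each element has `gene_sets` and `assays`.
#' @param n_sirnas siRNAs per gene.
#' @param controls_per_plate named counts of control wells per plate.
#' @param vehicle_signal named baseline vehicle luminescence per assay
#'   (arbitrary units; cancels in normalization).
#' @param treated_ratio named treated/vehicle baseline signal ratio per
#'   assay.
#' @param frac_negative,frac_positive planted regulator fractions.
#' @param effect_meanlog,effect_sdlog log-normal parameters of the latent
#'   effect strength s (caspase-3/7 effect is 1 + s for negative
#'   regulators, 1/(1 + s) for positive ones).
#' @param caspase8_coupling,viability_coupling scale of the caspase-8 and
#'   viability effects relative to the latent strength.
#' @param rho latent correlation between caspase and viability effect
#'   strengths of a gene.
#' @param eta_shape1,eta_shape2 Beta parameters of per-siRNA efficacy.
#' @param eta_fixed if non-`NULL`, every siRNA gets this efficacy instead
#'   of a Beta draw (failures still apply); useful for exact signal-model
#'   checks.
#' @param p_fail probability an siRNA fails (efficacy 0).
#' @param sigma_log sdlog of multiplicative well noise.
#' @param plate_scale_sdlog sdlog of the per-plate-by-assay scale factor.
#' @param flip_caspase_factor,flip_viability_factor treated-signal
#'   multipliers for the siFLIP control.
#' @param celldeath_viability_factor viability multiplier (both conditions)
#'   for the siCelldeath control.
#' @return validated list of class `screen_config`.
#' @export
screen_config <- function(
    n_genes = c(kinase = 691L, phosphatase = 206L, additional = 238L),
    batches = list(
      kinome_plus_additional = list(
        gene_sets = c("kinase", "additional"),
        assays = c("caspase8", "caspase3_7", "viability")),
      phosphatase = list(
        gene_sets = "phosphatase",
        assays = c("caspase3_7", "viability"))),
    n_sirnas = 4L,
    controls_per_plate = c(siNeg = 8L, cells_only = 4L, siCelldeath = 4L,
                           siCASP8 = 4L, siFLIP = 4L),
    vehicle_signal = c(caspase8 = 1000, caspase3_7 = 1000,
                       viability = 10000),
    treated_ratio = c(caspase8 = 2.25, caspase3_7 = 6.5, viability = 0.5),
    frac_negative = 0.13, frac_positive = 0.01,
    effect_meanlog = log(1.5), effect_sdlog = 0.5,
    caspase8_coupling = 0.45, viability_coupling = 1.2,
    rho = 0.7,
    eta_shape1 = 5, eta_shape2 = 1.5, eta_fixed = NULL, p_fail = 0.25,
    sigma_log = 0.28, plate_scale_sdlog = 0.1,
    flip_caspase_factor = 1.6, flip_viability_factor = 0.6,
    celldeath_viability_factor = 0.3) {
  cfg <- list(n_genes = n_genes, batches = batches, n_sirnas = n_sirnas,
              controls_per_plate = controls_per_plate,
              vehicle_signal = vehicle_signal, treated_ratio = treated_ratio,
              frac_negative = frac_negative, frac_positive = frac_positive,
              effect_meanlog = effect_meanlog, effect_sdlog = effect_sdlog,
              caspase8_coupling = caspase8_coupling,
              viability_coupling = viability_coupling, rho = rho,
              eta_shape1 = eta_shape1, eta_shape2 = eta_shape2,
              eta_fixed = eta_fixed,
              p_fail = p_fail, sigma_log = sigma_log,
              plate_scale_sdlog = plate_scale_sdlog,
              flip_caspase_factor = flip_caspase_factor,
              flip_viability_factor = flip_viability_factor,
              celldeath_viability_factor = celldeath_viability_factor)
  validate_screen_config(cfg)
}

validate_screen_config <- function(cfg) {
  probs <- c(frac_negative = cfg$frac_negative,
             frac_positive = cfg$frac_positive, p_fail = cfg$p_fail)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop_validation(paste("probabilities outside [0,1]:",
                          paste(names(probs)[bad], collapse = ", ")))
  if (cfg$frac_negative + cfg$frac_positive > 1)
    stop_validation("frac_negative + frac_positive exceeds 1")
  if (cfg$sigma_log < 0 || cfg$plate_scale_sdlog < 0)
    stop_validation("noise sdlog parameters must be >= 0")
  if (abs(cfg$rho) > 1) stop_validation("rho must lie in [-1, 1]")
  if (!is.null(cfg$eta_fixed) && (cfg$eta_fixed < 0 || cfg$eta_fixed > 1))
    stop_validation("eta_fixed must lie in [0, 1]")
  if (cfg$n_sirnas < 1L) stop_validation("n_sirnas must be >= 1")
  if (any(cfg$n_genes < 0L)) stop_validation("n_genes must be >= 0")
  needed <- unique(unlist(lapply(cfg$batches, `[[`, "gene_sets")))
  miss <- setdiff(needed, names(cfg$n_genes))
  if (length(miss))
    stop_validation(paste("batch references unknown gene set(s):",
                          paste(miss, collapse = ", ")))
  for (nm in c("vehicle_signal", "treated_ratio")) {
    assays <- unique(unlist(lapply(cfg$batches, `[[`, "assays")))
    miss <- setdiff(assays, names(cfg[[nm]]))
    if (length(miss))
      stop_validation(paste(nm, "missing assay(s):",
                            paste(miss, collapse = ", ")))
    if (any(cfg[[nm]] <= 0)) stop_validation(paste(nm, "must be > 0"))
  }
  n_ctrl <- sum(cfg$controls_per_plate)
  if (n_ctrl + cfg$n_sirnas > 384L)
    stop_validation("a plate cannot hold the controls plus one gene")
  structure(cfg, class = "screen_config")
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# sub-stream seed derived from a master seed; kept within 32-bit range
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629
}

well_labels_384 <- function() {
  sprintf("%s%02d", rep(LETTERS[1:16], each = 24L), rep(1:24, times = 16L))
}

# draw per-gene truths for one batch
draw_gene_truth <- function(cfg, gene_ids, gene_sets) {
  n <- length(gene_ids)
  u <- stats::runif(n)
  class <- ifelse(u < cfg$frac_negative, "negative_regulator",
                  ifelse(u < cfg$frac_negative + cfg$frac_positive,
                         "positive_regulator", "null"))
  z1 <- stats::rnorm(n)
  z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * stats::rnorm(n)
  s_casp <- exp(cfg$effect_meanlog + cfg$effect_sdlog * z1)
  s_viab <- exp(cfg$effect_meanlog + cfg$effect_sdlog * z2)
  e_c37 <- e_c8 <- e_viab <- rep(1, n)
  neg <- class == "negative_regulator"
  pos <- class == "positive_regulator"
  e_c37[neg] <- 1 + s_casp[neg]
  e_c8[neg] <- 1 + cfg$caspase8_coupling * s_casp[neg]
  e_viab[neg] <- 1 / (1 + cfg$viability_coupling * s_viab[neg])
  e_c37[pos] <- 1 / (1 + s_casp[pos])
  e_c8[pos] <- 1 / (1 + cfg$caspase8_coupling * s_casp[pos])
  # silencing a positive regulator protects: viability moves toward, but not
  # beyond, the vehicle level (multiplier capped at 1/treated_ratio)
  e_viab[pos] <- pmin(1 + cfg$viability_coupling * s_viab[pos],
                      1 / cfg$treated_ratio[["viability"]])
  s_casp[!(neg | pos)] <- NA_real_
  s_viab[!(neg | pos)] <- NA_real_
  data.frame(gene_id = gene_ids, gene_set = gene_sets, class = class,
             e_caspase8 = e_c8, e_caspase3_7 = e_c37, e_viability = e_viab,
             s_caspase = s_casp, s_viability = s_viab,
             stringsAsFactors = FALSE)
}

control_effect <- function(cfg, role, assay, condition) {
  ratio <- cfg$treated_ratio[[assay]]
  treated <- condition == "treated"
  caspase <- assay %in% c("caspase8", "caspase3_7")
  switch(role,
    siNeg = 1, cells_only = 1,
    siCASP8 = if (!treated) 1
      else if (caspase) 1 / ratio           # treated signal back to vehicle
      else 1 / ratio,                       # viability restored likewise
    siFLIP = if (!treated) 1
      else if (caspase) cfg$flip_caspase_factor
      else cfg$flip_viability_factor,
    siCelldeath = if (assay == "viability") cfg$celldeath_viability_factor
      else 1,
    1)
}

#' Simulate a raw arrayed screen with planted regulators
#'
#' Generates well-level raw luminescence for every batch, plate, assay and
#' condition of the configuration, together with the planted ground truth.
#' The signal model is
#' `raw = plate_scale x vehicle_signal[assay] x ratio(condition) x effect
#'  x exp(N(0, sigma_log))`,
#' where for a treated experimental well `effect = 1 + eta_i (e - 1)` with
#' `e` the gene's assay-specific effect and `eta_i` the siRNA's efficacy
#' (vehicle wells carry no effect: regulators here act only on the
#' ligand-induced component). Controls follow fixed behaviors: siCASP8
#' returns treated caspase signals and viability to vehicle level, siFLIP
#' amplifies treated caspase signals and deepens viability loss, and
#' siCelldeath reduces viability in both conditions. Each plate consumes
#' its own random sub-stream derived from `seed`, so output is reproducible
#' plate by plate.
#'
#' @param config a [screen_config()] object.
#' @param seed integer master seed.
#' @return list with `wells` (validated well records), `truth` (per-gene
#'   class and per-assay effects), `sirna_truth` (per-siRNA efficacy and
#'   failure flags) and `annotation` (gene_id, gene_set).
#' @export
simulate_screen <- function(config, seed) {
  cfg <- validate_screen_config(config)
  set_prefix <- c(kinase = "KIN", phosphatase = "PHO", additional = "ADD")

  gene_tables <- with_local_seed(derive_seed(seed, 0L), {
    lapply(names(cfg$batches), function(bn) {
      sets <- cfg$batches[[bn]]$gene_sets
      ids <- unlist(lapply(sets, function(gs) {
        pre <- if (gs %in% names(set_prefix)) set_prefix[[gs]]
        else toupper(substr(gs, 1, 3))
        sprintf("%s%04d", pre, seq_len(cfg$n_genes[[gs]]))
      }))
      gsets <- rep(sets, cfg$n_genes[sets])
      truth <- draw_gene_truth(cfg, ids, gsets)
      eta <- if (is.null(cfg$eta_fixed))
        matrix(stats::rbeta(length(ids) * cfg$n_sirnas,
                            cfg$eta_shape1, cfg$eta_shape2),
               nrow = length(ids))
      else matrix(cfg$eta_fixed, nrow = length(ids), ncol = cfg$n_sirnas)
      failed <- matrix(stats::runif(length(ids) * cfg$n_sirnas) < cfg$p_fail,
                       nrow = length(ids))
      eta[failed] <- 0
      list(truth = truth, eta = eta, failed = failed)
    })
  })
  names(gene_tables) <- names(cfg$batches)

  n_ctrl <- sum(cfg$controls_per_plate)
  capacity <- (384L - n_ctrl) %/% cfg$n_sirnas
  wells384 <- well_labels_384()
  sirna_labels <- LETTERS[seq_len(cfg$n_sirnas)]

  all_rows <- list()
  plate_counter <- 0L
  for (bn in names(cfg$batches)) {
    bt <- gene_tables[[bn]]
    assays <- cfg$batches[[bn]]$assays
    n_genes_b <- nrow(bt$truth)
    n_plates <- ceiling(n_genes_b / capacity)
    for (p in seq_len(n_plates)) {
      plate_counter <- plate_counter + 1L
      plate_id <- sprintf("%s_P%02d", bn, p)
      gidx <- ((p - 1L) * capacity + 1L):min(p * capacity, n_genes_b)
      ng <- length(gidx)

      role <- c(rep(names(cfg$controls_per_plate), cfg$controls_per_plate),
                rep("experimental", ng * cfg$n_sirnas))
      gene <- c(rep("", n_ctrl),
                rep(bt$truth$gene_id[gidx], each = cfg$n_sirnas))
      sirna <- c(rep("", n_ctrl),
                 rep(sirna_labels, times = ng))
      eta <- c(rep(NA_real_, n_ctrl),
               as.vector(t(bt$eta[gidx, , drop = FALSE])))
      well <- wells384[seq_along(role)]
      nw <- length(role)

      plate_rows <- with_local_seed(derive_seed(seed, plate_counter), {
        rows <- list()
        for (assay in assays) {
          scale <- stats::rlnorm(1, 0, cfg$plate_scale_sdlog)
          e_assay <- c(rep(NA_real_, n_ctrl),
                       rep(bt$truth[[paste0("e_", assay)]][gidx],
                           each = cfg$n_sirnas))
          for (condition in c("vehicle", "treated")) {
            ratio <- if (condition == "treated")
              cfg$treated_ratio[[assay]] else 1
            effect <- ifelse(
              role == "experimental",
              if (condition == "treated") 1 + eta * (e_assay - 1) else 1,
              vapply(role, control_effect, numeric(1), cfg = cfg,
                     assay = assay, condition = condition))
            noise <- exp(stats::rnorm(nw, 0, cfg$sigma_log))
            raw <- scale * cfg$vehicle_signal[[assay]] * ratio *
              effect * noise
            rows[[paste(assay, condition)]] <- data.frame(
              screen_batch = bn, plate_id = plate_id, well = well,
              sample_role = role, gene_id = gene, sirna_id = sirna,
              condition = condition, assay = assay, raw_signal = raw,
              stringsAsFactors = FALSE)
          }
        }
        rows
      })
      all_rows[[plate_id]] <- do.call(rbind, plate_rows)
    }
  }
  wells <- do.call(rbind, all_rows)
  rownames(wells) <- NULL

  truth <- do.call(rbind, lapply(gene_tables, `[[`, "truth"))
  rownames(truth) <- NULL
  sirna_truth <- do.call(rbind, lapply(names(gene_tables), function(bn) {
    bt <- gene_tables[[bn]]
    data.frame(
      gene_id = rep(bt$truth$gene_id, each = cfg$n_sirnas),
      sirna_id = rep(sirna_labels, times = nrow(bt$truth)),
      eta = as.vector(t(bt$eta)),
      failed = as.vector(t(bt$failed)),
      stringsAsFactors = FALSE)
  }))
  rownames(sirna_truth) <- NULL

  list(wells = validate_well_records(wells), truth = truth,
       sirna_truth = sirna_truth,
       annotation = truth[, c("gene_id", "gene_set")])
}

#' Recovery of planted regulators by the hit caller
#'
#' Confusion counts and derived metrics of gene calls against the simulator
#' ground truth, per stringency tier. At tier "+" only high-stringency calls
#' count as predicted positives; at tier "(+)" a call at either stringency
#' counts. Precision is `NA` when nothing is called.
#'
#' @param calls [call_screen()] output.
#' @param truth simulator truth table.
#' @param target_class truth class treated as positive (default
#'   `"negative_regulator"`).
#' @return data.frame per tier: tp, fp, fn, tn, sensitivity, precision,
#'   specificity.
#' @export
evaluate_recovery <- function(calls, truth,
                              target_class = "negative_regulator") {
  if (!setequal(calls$gene_id, truth$gene_id))
    stop_validation("calls and truth cover different gene universes")
  idx <- match(calls$gene_id, truth$gene_id)
  is_true <- truth$class[idx] == target_class
  rows <- lapply(c(high = "+", low = "(+)"), function(sym) {
    pred <- if (sym == "+") calls$tier == "+"
    else calls$tier %in% c("+", "(+)")
    tp <- sum(pred & is_true); fp <- sum(pred & !is_true)
    fn <- sum(!pred & is_true); tn <- sum(!pred & !is_true)
    data.frame(
      tier = sym, tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
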