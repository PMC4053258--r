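# SD thresholds, siRNA flagging, the m-of-n gene rule, corroboration,
# ranking and the secondary-screen matrix.

# wells with given siNeg treated fold changes and per-gene siRNA values
screen_from_values <- function(sineg_treated, gene_values,
                               assay = "caspase3_7", batch = "b1") {
  genes <- names(gene_values)
  labels <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24), 1:24)
  n_veh <- max(2, length(sineg_treated))
  n_trt <- length(sineg_treated)
  n_exp <- sum(lengths(gene_values))
  rbind(
    make_wells(batch = batch, role = "siNeg", gene = "", sirna = "",
               condition = "vehicle", assay = assay,
               signal = rep(1000, n_veh), well = labels[seq_len(n_veh)]),
    make_wells(batch = batch, role = "siNeg", gene = "", sirna = "",
               condition = "treated", assay = assay,
               signal = sineg_treated * 1000,
               well = labels[seq_len(n_trt)]),
    make_wells(batch = batch, role = "experimental", assay = assay,
               gene = rep(genes, lengths(gene_values)),
               sirna = unlist(lapply(gene_values, function(v)
                 LETTERS[seq_along(v)])),
               condition = "treated",
               signal = unlist(gene_values) * 1000,
               well = labels[n_trt + seq_len(n_exp)]))
}

test_that("control stats match hand arithmetic and stay ordered", {
  wells <- screen_from_values(c(8, 10, 12), list(G1 = 15))
  norm <- normalize_to_plate_control(wells)
  cs <- compute_control_stats(norm, "b1", "caspase3_7")
  expect_equal(cs$mu, 10)
  expect_equal(cs$sigma, 2)
  expect_equal(unname(cs$t_up), c(12, 14))
  expect_equal(unname(cs$t_down), c(8, 6))
  # symmetry: T_up(k) + T_down(k) = 2 mu, exactly
  expect_identical(unname(cs$t_up + cs$t_down), c(20, 20))

  # constant controls: degenerate but legal
  wells0 <- screen_from_values(c(7, 7, 7), list(G1 = 15))
  cs0 <- compute_control_stats(normalize_to_plate_control(wells0),
                               "b1", "caspase3_7")
  expect_equal(cs0$sigma, 0)
  expect_equal(unname(cs0$t_up), c(7, 7))

  # fewer than two control wells is an error
  wells1 <- screen_from_values(5, list(G1 = 15))
  expect_error(compute_control_stats(normalize_to_plate_control(wells1),
                                     "b1", "caspase3_7"), ">= 2")
})

test_that("flags use strict inequalities at the thresholds", {
  wells <- screen_from_values(c(8, 10, 12),
                              list(G1 = c(14, 14.0001, 12, 8, 6, 5.9999)))
  norm <- normalize_to_plate_control(wells)
  cs <- compute_control_stats(norm, "b1", "caspase3_7")
  flags <- flag_sirnas(aggregate_sirna(norm), cs)
  flags <- flags[order(flags$sirna_id), ]
  # values: A=14 (== T_up2), B=14.0001, C=12 (== T_up1), D=8 (== T_down1),
  # E=6 (== T_down2), F=5.9999
  expect_equal(flags$flag_up_k2, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(flags$flag_up_k1, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(flags$flag_down_k1, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(flags$flag_down_k2, c(FALSE, FALSE, FALSE, FALSE, FALSE,
                                     TRUE))
  expect_error(flag_sirnas(transform(aggregate_sirna(norm),
                                     screen_batch = "other"), cs),
               "does not match")
})

test_that("random flag patterns match a brute-force comparison loop", {
  set.seed(21)
  for (i in 1:20) {
    f <- runif(10, 0, 20)
    wells <- screen_from_values(runif(4, 5, 9), list(G1 = f))
    norm <- normalize_to_plate_control(wells)
    cs <- compute_control_stats(norm, "b1", "caspase3_7")
    flags <- flag_sirnas(aggregate_sirna(norm), cs)
    ocs <- oracle_control_stats(norm, "b1", "caspase3_7")
    for (j in seq_len(nrow(flags))) {
      expect_identical(flags$flag_up_k2[j],
                       flags$fold_change[j] > ocs$t_up[["k2"]])
      expect_identical(flags$flag_down_k1[j],
                       flags$fold_change[j] < ocs$t_down[["k1"]])
    }
    # 2-SD flags imply 1-SD flags; up and down exclusive when sigma > 0
    expect_true(all(flags$flag_up_k1 | !flags$flag_up_k2))
    expect_true(all(flags$flag_down_k1 | !flags$flag_down_k2))
    expect_false(any(flags$flag_up_k1 & flags$flag_down_k1))
  }
})

test_that("the 3-of-4 rule qualifies exactly the right flag patterns", {
  base <- data.frame(gene_id = "G", assay = "caspase3_7",
                     sirna_id = LETTERS[1:4], stringsAsFactors = FALSE)
  n_high <- 0
  for (pattern in 0:15) {
    k2 <- as.logical(bitwAnd(pattern, 2^(0:3)))
    flags <- base
    flags$flag_up_k2 <- k2
    flags$flag_up_k1 <- k2          # k1 never below k2
    flags$flag_down_k1 <- flags$flag_down_k2 <- FALSE
    call <- call_gene(flags, m = 3, direction = "up")
    expect_identical(call$tier == "+", sum(k2) >= 3)
    n_high <- n_high + (call$tier == "+")
  }
  expect_equal(n_high, 5)  # C(4,3) + C(4,4)

  # low tier engages when only 1-SD flags reach m
  flags <- base
  flags$flag_up_k2 <- c(TRUE, TRUE, FALSE, FALSE)
  flags$flag_up_k1 <- c(TRUE, TRUE, TRUE, FALSE)
  flags$flag_down_k1 <- flags$flag_down_k2 <- FALSE
  expect_equal(call_gene(flags, direction = "up")$tier, "(+)")
  flags$flag_up_k1 <- flags$flag_up_k2
  expect_equal(call_gene(flags, direction = "up")$tier, "-")

  # fewer reagents than m: uncallable, tier forced to "-"
  short <- call_gene(flags[1:2, ], m = 3, direction = "up")
  expect_false(short$callable)
  expect_equal(short$tier, "-")
  expect_error(call_gene(flags[0, ], direction = "up"), "empty")
})

test_that("call_screen equals a naive loop reimplementation", {
  set.seed(22)
  for (i in 1:6) {
    wells <- random_screen(n_genes = sample(5:12, 1),
                           n_plates = sample(1:2, 1))
    # spike some genes so both tiers occur
    boost <- wells$sample_role == "experimental" &
      wells$condition == "treated" &
      wells$gene_id %in% c("G01", "G02")
    wells$raw_signal[boost] <- wells$raw_signal[boost] * 15
    norm <- normalize_to_plate_control(wells)
    for (direction in c("up", "down")) {
      got <- call_screen(norm, NULL, assay = "caspase3_7",
                         direction = direction)
      want <- oracle_call_screen(norm, "caspase3_7", direction)
      expect_equal(got$gene_id, want$gene_id)
      expect_equal(got$n_k1, want$n_k1)
      expect_equal(got$n_k2, want$n_k2)
      expect_equal(got$tier, want$tier)
    }
  }
})

test_that("batches are called against their own thresholds", {
  set.seed(23)
  w1 <- random_screen(n_genes = 6, batch = "alpha")
  w2 <- random_screen(n_genes = 6, batch = "beta")
  # make beta's controls much tighter so its thresholds differ
  pick <- w2$sample_role == "siNeg" & w2$condition == "treated"
  w2$raw_signal[pick] <- 1000 * (1 + 0.001 * seq_len(sum(pick)))
  norm <- normalize_to_plate_control(rbind(w1, w2))
  calls <- call_screen(norm, NULL, assay = "caspase3_7", direction = "up")
  cs <- attr(calls, "control_stats")
  expect_named(cs, c("alpha", "beta"))
  expect_false(isTRUE(all.equal(cs$alpha$sigma, cs$beta$sigma)))
  want <- oracle_call_screen(norm, "caspase3_7", "up")
  expect_equal(calls$tier, want$tier)
})

test_that("raising k or m never enlarges the call set", {
  set.seed(24)
  wells <- random_screen(n_genes = 20, n_sineg = 8)
  boost <- wells$sample_role == "experimental" &
    wells$condition == "treated" &
    wells$gene_id %in% sprintf("G%02d", 1:8)
  wells$raw_signal[boost] <- wells$raw_signal[boost] * runif(sum(boost), 2, 20)
  norm <- normalize_to_plate_control(wells)
  calls3 <- call_screen(norm, NULL, assay = "caspase3_7", direction = "up",
                        m = 3)
  calls4 <- call_screen(norm, NULL, assay = "caspase3_7", direction = "up",
                        m = 4)
  # tier consistency within a call
  expect_true(all(calls3$n_k1 >= calls3$n_k2))
  # m = 4 calls are a subset of m = 3 calls, tier by tier
  high3 <- calls3$gene_id[calls3$tier == "+"]
  high4 <- calls4$gene_id[calls4$tier == "+"]
  expect_true(all(high4 %in% high3))
  called3 <- calls3$gene_id[calls3$tier != "-"]
  called4 <- calls4$gene_id[calls4$tier != "-"]
  expect_true(all(called4 %in% called3))
  # k = 2 qualifiers are a subset of k = 1 qualifiers gene-wise
  expect_true(all(calls3$n_k2 <= calls3$n_k1))
})

test_that("unannotated genes are called with gene_set 'unknown'", {
  set.seed(25)
  wells <- random_screen(n_genes = 4)
  norm <- normalize_to_plate_control(wells)
  ann <- data.frame(gene_id = c("G01", "G02"), gene_set = "kinase")
  expect_warning(calls <- call_screen(norm, ann, assay = "caspase3_7",
                                      direction = "up"),
                 "G03")
  expect_setequal(calls$gene_set[calls$gene_id %in% c("G03", "G04")],
                  "unknown")
  expect_equal(nrow(calls), 4)
  tal <- tally_calls(calls)
  expect_setequal(tal$gene_set, c("kinase", "unknown"))
  expect_equal(sum(tal$n_genes), 4)
})

test_that("corroboration derives from the three calls and recomputes", {
  fake_calls <- function(genes, tiers, n_k1 = NULL) {
    data.frame(gene_id = genes, tier = tiers,
               n_k1 = if (is.null(n_k1)) ifelse(tiers == "-", 0L, 3L)
               else n_k1,
               stringsAsFactors = FALSE)
  }
  primary <- fake_calls(c("A", "B", "C"), c("+", "+", "(+)"))
  viab <- fake_calls(c("A", "B", "C"), c("+", "(+)", "-"))
  c8 <- fake_calls(c("A", "B"), c("(+)", "-"), n_k1 = c(3L, 1L))
  rec <- corroborate_calls(primary, viab, c8)
  expect_equal(rec$n_assays_supporting, c(2L, 0L, 0L))
  expect_equal(rec$viability_supports, c(TRUE, FALSE, FALSE))
  expect_equal(rec$viability_supports_relaxed, c(TRUE, TRUE, FALSE))
  expect_equal(rec$caspase8_supports, c(TRUE, FALSE, FALSE))
  expect_equal(rec$complete, c(TRUE, TRUE, FALSE))
  # missing assay entirely: incomplete records, no exception
  rec2 <- corroborate_calls(primary, NULL, NULL)
  expect_true(all(!rec2$complete))
  expect_true(all(rec2$n_assays_supporting == 0L))

  # randomized tables: support re-derives from the counts
  set.seed(26)
  for (i in 1:10) {
    g <- sprintf("g%d", 1:6)
    pc <- fake_calls(g, sample(c("+", "(+)", "-"), 6, TRUE))
    vc <- fake_calls(g, sample(c("+", "(+)", "-"), 6, TRUE))
    cc <- fake_calls(g, sample(c("+", "(+)", "-"), 6, TRUE),
                     n_k1 = sample(0:4, 6, TRUE))
    rec <- corroborate_calls(pc, vc, cc)
    expect_equal(rec$n_assays_supporting,
                 as.integer(vc$tier == "+") + as.integer(cc$n_k1 >= 3))
  }
})

test_that("median ranking is descending with lexicographic ties", {
  agg <- data.frame(
    screen_batch = "b1",
    gene_id = rep(c("Gb", "Ga", "Gc", "Gd"), each = 4),
    sirna_id = rep(LETTERS[1:4], 4),
    assay = "caspase3_7", condition = "treated",
    fold_change = c(11, 13, 12, 14,      # Gb: median 12.5
                    2, 4, 6, 8,          # Ga: median 5 (middle pair mean)
                    19, 21, 20, 22,      # Gc: median 20.5
                    3, 7, 4, 6),         # Gd: median 5, ties with Ga
    stringsAsFactors = FALSE)
  r <- rank_by_median(agg, "caspase3_7")
  expect_equal(r$gene_id, c("Gc", "Gb", "Ga", "Gd"))
  expect_equal(r$median_fold_change, c(20.5, 12.5, 5, 5))
  expect_equal(r$rank, 1:4)

  # against an independent sort
  set.seed(27)
  for (i in 1:5) {
    agg2 <- agg
    agg2$fold_change <- runif(16, 1, 30)
    r2 <- rank_by_median(agg2, "caspase3_7")
    med <- vapply(split(agg2$fold_change, agg2$gene_id), median, 0)
    want <- names(sort(-med))
    expect_equal(r2$gene_id[order(r2$gene_id)], sort(want))
    expect_true(all(diff(r2$median_fold_change) <= 0))
  }
})

test_that("the secondary matrix calls each line on its own controls", {
  set.seed(28)
  make_line <- function(hot_genes, mult) {
    w <- random_screen(n_genes = 6, n_sineg = 8)
    pick <- w$sample_role == "experimental" & w$condition == "treated" &
      w$gene_id %in% hot_genes
    w$raw_signal[pick] <- w$raw_signal[pick] * mult
    normalize_to_plate_control(w)
  }
  lines <- list(sensitive = make_line(c("G01", "G02"), 40),
                resistant = make_line(character(), 1))
  mat <- secondary_matrix(lines)
  expect_equal(dim(mat), c(6L, 2L))
  expect_equal(unname(mat["G01", "sensitive"]), "+")
  expect_true(all(mat[, "resistant"] %in% c("-", "(+)")))
  counts <- attr(mat, "n_high_per_line")
  expect_equal(unname(counts["sensitive"]), sum(mat[, "sensitive"] == "+"))

  # row-order shuffling of the input leaves the matrix unchanged
  shuffled <- lapply(lines, function(d) d[sample(nrow(d)), ])
  expect_identical(secondary_matrix(shuffled), mat)

  # a gene absent from one line is NA, not "-"
  drop1 <- lines
  drop1$resistant <- drop1$resistant[drop1$resistant$gene_id != "G05" |
                                       drop1$resistant$sample_role !=
                                       "experimental", ]
  mat2 <- secondary_matrix(drop1)
  expect_true(is.na(mat2["G05", "resistant"]))
  expect_false(is.na(mat2["G05", "sensitive"]))
})
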