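# Independent brute-force oracles and small dataset builders. Everything
# here is written against the definitions, not the package's code paths:
# explicit loops, no shared helpers.

# build a one-plate (or multi-plate) well table by hand
make_wells <- function(batch = "b1", plate = "p1", assay = "caspase3_7",
                       condition = "treated", role = "experimental",
                       gene = "G1", sirna = "A", signal = 1000,
                       well = NULL) {
  n <- max(lengths(list(plate, assay, condition, role, gene, sirna,
                        signal)))
  df <- data.frame(screen_batch = batch, plate_id = plate,
                   well = if (is.null(well)) NA_character_ else well,
                   sample_role = role, gene_id = gene, sirna_id = sirna,
                   condition = condition, assay = assay,
                   raw_signal = signal, stringsAsFactors = FALSE)
  if (is.null(well)) {
    labels <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24), 1:24)
    key <- paste(df$plate_id, df$assay, df$condition)
    df$well <- stats::ave(seq_len(nrow(df)), key,
                          FUN = seq_along)
    df$well <- labels[df$well]
  }
  df$gene_id[df$sample_role != "experimental"] <- ""
  df$sirna_id[df$sample_role != "experimental"] <- ""
  df
}

# a random small screen: one batch, genes x 4 siRNAs + siNeg controls, both
# conditions, chosen assays
random_screen <- function(n_genes = 8, n_sineg = 6, n_plates = 2,
                          assays = "caspase3_7", batch = "b1") {
  genes <- sprintf("G%02d", seq_len(n_genes))
  plate_of <- rep_len(sprintf("%s_p%d", batch, seq_len(n_plates)), n_genes)
  rows <- list()
  for (a in assays) for (cond in c("vehicle", "treated")) {
    for (p in unique(plate_of)) {
      g <- genes[plate_of == p]
      rows[[length(rows) + 1L]] <- make_wells(
        batch = batch, plate = p, assay = a, condition = cond,
        role = c(rep("siNeg", n_sineg),
                 rep("experimental", length(g) * 4)),
        gene = c(rep("", n_sineg), rep(g, each = 4)),
        sirna = c(rep("", n_sineg), rep(LETTERS[1:4], length(g))),
        signal = exp(rnorm(n_sineg + length(g) * 4, log(1000), 0.5)))
    }
  }
  do.call(rbind, rows)
}

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# loop-based control stats from raw well records
oracle_control_stats <- function(norm, batch, assay, condition = "treated") {
  vals <- c()
  for (i in seq_len(nrow(norm))) {
    r <- norm[i, ]
    if (r$screen_batch == batch && r$assay == assay &&
        r$condition == condition && r$sample_role == "siNeg")
      vals <- c(vals, r$fold_change)
  }
  mu <- mean(vals)
  sigma <- oracle_sd(vals)
  list(mu = mu, sigma = sigma,
       t_up = c(k1 = mu + sigma, k2 = mu + 2 * sigma),
       t_down = c(k1 = mu - sigma, k2 = mu - 2 * sigma))
}

# loop-based screen caller, straight from the rule's definition
oracle_call_screen <- function(norm, assay, direction, m = 3,
                               condition = "treated") {
  out <- list()
  for (batch in sort(unique(norm$screen_batch))) {
    st <- oracle_control_stats(norm, batch, assay, condition)
    sub <- norm[norm$screen_batch == batch & norm$assay == assay &
                  norm$condition == condition &
                  norm$sample_role == "experimental", ]
    for (gene in sort(unique(sub$gene_id))) {
      gsub <- sub[sub$gene_id == gene, ]
      n_k1 <- n_k2 <- n <- 0
      for (sirna in unique(gsub$sirna_id)) {
        f <- mean(gsub$fold_change[gsub$sirna_id == sirna])
        n <- n + 1
        hit1 <- if (direction == "up") f > st$t_up[["k1"]]
        else f < st$t_down[["k1"]]
        hit2 <- if (direction == "up") f > st$t_up[["k2"]]
        else f < st$t_down[["k2"]]
        n_k1 <- n_k1 + hit1
        n_k2 <- n_k2 + hit2
      }
      tier <- if (n < m) "-" else if (n_k2 >= m) "+"
      else if (n_k1 >= m) "(+)" else "-"
      out[[paste(batch, gene)]] <- data.frame(
        screen_batch = batch, gene_id = gene, n = n, n_k1 = n_k1,
        n_k2 = n_k2, tier = tier, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$screen_batch, res$gene_id), ]
  rownames(res) <- NULL
  res
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_welch <- function(a, b) {
  va <- oracle_sd(a)^2 / length(a)
  vb <- oracle_sd(b)^2 / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_z_factor <- function(pos, neg) {
  1 - 3 * (oracle_sd(pos) + oracle_sd(neg)) / abs(mean(pos) - mean(neg))
}
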