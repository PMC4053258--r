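# Well-level screen data: validation, I/O and per-plate control normalization.

#' @keywords internal
"_PACKAGE"

SAMPLE_ROLES <- c("experimental", "cells_only", "siNeg", "siCelldeath",
                  "siCASP8", "siFLIP")
CONDITIONS <- c("vehicle", "treated")
ASSAYS <- c("caspase8", "caspase3_7", "viability")
GENE_SETS <- c("kinase", "phosphatase", "additional")

WELL_COLUMNS <- c("screen_batch", "plate_id", "well", "sample_role",
                  "gene_id", "sirna_id", "condition", "assay", "raw_signal")

#' Parse and canonicalize 384-well coordinates
#'
#' Well labels combine a row letter (A--P) and a column number (1--24).
#' Unpadded input such as `"B7"` is accepted; the canonical form is
#' zero-padded (`"B07"`).
#'
#' @param well character vector of well labels.
#' @return character vector of canonical labels; invalid entries are `NA`.
#' @examples
#' parse_well(c("B7", "b07", "P24", "Q01"))
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  vapply(m, function(parts) {
    if (length(parts) != 3L) return(NA_character_)
    col <- as.integer(parts[3L])
    if (col < 1L || col > 24L) return(NA_character_)
    sprintf("%s%02d", parts[2L], col)
  }, character(1))
}

stop_validation <- function(msg, rows = NULL) {
  if (!is.null(rows) && length(rows)) {
    shown <- utils::head(rows, 10L)
    msg <- sprintf("%s [rows: %s%s]", msg, paste(shown, collapse = ", "),
                   if (length(rows) > 10L) ", ..." else "")
  }
  stop(errorCondition(msg, class = c("screen_validation_error", "error")))
}

#' Validate a table of well-level measurements
#'
#' Checks the constraints every downstream step relies on: required columns,
#' strictly positive signals, parseable 384-well coordinates, role/gene
#' consistency (experimental wells and only experimental wells carry a gene
#' and siRNA label), known role/condition/assay levels, and uniqueness of
#' (plate, well, assay, condition). Well labels are canonicalized.
#'
#' @param records data.frame with the columns listed in the long-format
#'   screen table: screen_batch, plate_id, well, sample_role, gene_id,
#'   sirna_id, condition, assay, raw_signal.
#' @return the validated data.frame, wells in canonical zero-padded form.
#' @export
validate_well_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(WELL_COLUMNS, names(records))
  if (length(missing_cols))
    stop_validation(paste("missing column(s):",
                          paste(missing_cols, collapse = ", ")))
  for (col in c("gene_id", "sirna_id"))
    records[[col]][is.na(records[[col]])] <- ""

  bad <- which(is.na(records$raw_signal) | records$raw_signal <= 0)
  if (length(bad)) stop_validation("raw_signal must be > 0", bad)

  canon <- parse_well(records$well)
  bad <- which(is.na(canon))
  if (length(bad)) stop_validation("unparseable well coordinate", bad)
  records$well <- canon

  for (spec in list(list("sample_role", SAMPLE_ROLES),
                    list("condition", CONDITIONS),
                    list("assay", ASSAYS))) {
    bad <- which(!records[[spec[[1L]]]] %in% spec[[2L]])
    if (length(bad))
      stop_validation(sprintf("unknown %s value", spec[[1L]]), bad)
  }

  is_exp <- records$sample_role == "experimental"
  has_gene <- nzchar(records$gene_id)
  has_sirna <- nzchar(records$sirna_id)
  bad <- which((is_exp & !(has_gene & has_sirna)) |
                 (!is_exp & (has_gene | has_sirna)))
  if (length(bad))
    stop_validation(
      "experimental wells must carry gene_id and sirna_id; control wells must not",
      bad)

  key <- paste(records$plate_id, records$well, records$assay,
               records$condition, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_validation("duplicate (plate_id, well, assay, condition)", dup)

  records
}

#' Read a long-format screen table
#'
#' Reads well-level luminescence measurements from CSV or TSV (delimiter
#' inferred from the extension, `.tsv`/`.txt` meaning tab). If the table
#' lacks the annotation columns (sample_role, gene_id, sirna_id), a plate-map
#' CSV keyed by (plate_id, well) supplies them.
#'
#' @param path screen table path.
#' @param layout optional plate-map CSV with columns plate_id, well,
#'   sample_role, gene_id, sirna_id.
#' @param quiet suppress the ingestion summary message.
#' @return validated data.frame of well records.
#' @export
read_screen_table <- function(path, layout = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop_validation(paste("file not found:", path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  records <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  if (!is.null(layout)) {
    map <- utils::read.csv(layout, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("plate_id", "well", "sample_role", "gene_id", "sirna_id")
    miss <- setdiff(need, names(map))
    if (length(miss))
      stop_validation(paste("plate map missing column(s):",
                            paste(miss, collapse = ", ")))
    map$well <- parse_well(map$well)
    records$well <- parse_well(records$well)
    idx <- match(paste(records$plate_id, records$well),
                 paste(map$plate_id, map$well))
    if (anyNA(idx))
      stop_validation("wells absent from plate map", which(is.na(idx)))
    for (col in c("sample_role", "gene_id", "sirna_id"))
      records[[col]] <- map[[col]][idx]
  }
  if ("raw_signal" %in% names(records))
    records$raw_signal <- as.numeric(records$raw_signal)
  records <- validate_well_records(records)
  if (!quiet) {
    role_tab <- table(records$sample_role)
    message(sprintf(
      "read %d wells (%d plates); roles: %s", nrow(records),
      length(unique(records$plate_id)),
      paste(names(role_tab), role_tab, sep = "=", collapse = ", ")))
  }
  records
}

#' Write a screen table
#'
#' Emits the long-format table with a fixed column order so that a
#' write-then-read round trip reproduces the records exactly. A
#' `fold_change` column, when present, is appended after `raw_signal`.
#'
#' @param records well records, raw or normalized.
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(records, path) {
  cols <- c(WELL_COLUMNS, intersect("fold_change", names(records)))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records[, cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Normalize wells to the plate's untreated negative-control mean
#'
#' For every plate x assay, each raw signal is divided by the mean raw signal
#' of that plate x assay's siNeg vehicle (no-TRAIL) wells, giving the fold
#' change F used by all downstream analysis. Control wells are normalized and
#' retained; they are needed later for threshold estimation and QC.
#'
#' @param records validated well records.
#' @return the records with a `fold_change` column added.
#' @export
normalize_to_plate_control <- function(records) {
  records <- validate_well_records(records)
  key <- paste(records$plate_id, records$assay, sep = "\r")
  is_ref <- records$sample_role == "siNeg" & records$condition == "vehicle"
  ref_mean <- tapply(records$raw_signal[is_ref], key[is_ref], mean)
  denom <- ref_mean[key]
  if (anyNA(denom)) {
    bad <- unique(sub("\r", " / ", key[is.na(denom)]))
    stop_validation(paste("no siNeg vehicle wells for plate x assay:",
                          paste(bad, collapse = "; ")))
  }
  records$fold_change <- records$raw_signal / as.numeric(denom)
  records
}

#' Average replicate wells per siRNA
#'
#' Collapses normalized measurements to one record per
#' (screen_batch, gene, siRNA, assay, condition), averaging the fold change
#' over replicate wells. Primary screens place one siRNA per well, so this is
#' an identity pass there; it generalizes to designs with replicates.
#' Control wells (no gene label) are dropped here; they are consumed
#' separately by threshold estimation.
#'
#' @param measurements normalized well records (with `fold_change`).
#' @return data.frame with columns screen_batch, gene_id, sirna_id, assay,
#'   condition, fold_change, n_wells.
#' @export
aggregate_sirna <- function(measurements) {
  if (!"fold_change" %in% names(measurements))
    stop_validation("input must be normalized (fold_change column missing)")
  exp <- measurements[measurements$sample_role == "experimental", ]
  if (!nrow(exp))
    return(data.frame(screen_batch = character(), gene_id = character(),
                      sirna_id = character(), assay = character(),
                      condition = character(), fold_change = numeric(),
                      n_wells = integer()))
  out <- stats::aggregate(
    fold_change ~ screen_batch + gene_id + sirna_id + assay + condition,
    data = exp, FUN = mean)
  counts <- stats::aggregate(
    cbind(n_wells = fold_change) ~ screen_batch + gene_id + sirna_id +
      assay + condition,
    data = exp, FUN = length)
  out$n_wells <- as.integer(counts$n_wells)
  out[order(out$screen_batch, out$gene_id, out$sirna_id, out$assay,
            out$condition), , drop = FALSE]
}

#' Read a gene-set annotation table
#'
#' @param path CSV with columns gene_id, gene_set and optionally n_sirnas.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param annotation annotation data.frame to validate in place of a file.
#' @export
validate_annotation <- function(annotation) {
  if (!all(c("gene_id", "gene_set") %in% names(annotation)))
    stop_validation("annotation needs gene_id and gene_set columns")
  dup <- which(duplicated(annotation$gene_id))
  if (length(dup)) stop_validation("duplicated gene_id in annotation", dup)
  if (!"n_sirnas" %in% names(annotation)) annotation$n_sirnas <- 4L
  annotation
}
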