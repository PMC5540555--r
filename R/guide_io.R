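# Default column roles for Azimuth-style guide tables.
.default_column_map <- function() {
  list(
    sequence                = "30mer",
    gene_id                 = "Target gene",
    activity_score          = "score_drug_gene_rank",
    percent_peptide         = "Percent Peptide",
    amino_acid_cut_position = "Amino Acid Cut position"
  )
}

#' Validate a 30-mer guide context sequence
#'
#' A guide context is the 30-nucleotide window around a SpCas9 target site:
#' 4 nt upstream, the 20-nt protospacer, the NGG PAM (the two G's at
#' positions 26-27) and 3 nt downstream. The validator enforces length and
#' alphabet, uppercases, and optionally warns when positions 26-27 are not
#' "GG" (exploratory non-PAM inputs are legal, so this is never an error).
#'
#' @param raw_sequence character vector of candidate sequences.
#' @param warn_pam warn when positions 26-27 differ from "GG"?
#' @return the validated, uppercased sequences.
#' @examples
#' validate_guide(strrep("acgt", 7L) |> paste0("ac"))
#' @export
validate_guide <- function(raw_sequence, warn_pam = FALSE) {
  if (!is.character(raw_sequence)) {
    stop("`raw_sequence` must be a character vector", call. = FALSE)
  }
  seqs <- toupper(raw_sequence)
  bad_len <- nchar(seqs) != 30L
  if (any(bad_len)) {
    offender <- raw_sequence[bad_len][1L]
    stop(sprintf(
      "guide sequence must be exactly 30 nt, got %d: '%s'",
      nchar(offender), offender
    ), call. = FALSE)
  }
  bad_chr <- grepl("[^ACGT]", seqs)
  if (any(bad_chr)) {
    offender <- seqs[bad_chr][1L]
    stop(sprintf(
      "guide sequence contains non-ACGT characters (DNA expected): '%s'",
      offender
    ), call. = FALSE)
  }
  if (warn_pam) {
    no_pam <- substr(seqs, 26L, 27L) != "GG"
    if (any(no_pam)) {
      warning(sprintf(
        "%d sequence(s) lack 'GG' at positions 26-27 (no NGG PAM)",
        sum(no_pam)
      ), call. = FALSE)
    }
  }
  seqs
}

#' Construct a guide dataset
#'
#' A guide dataset is a data frame with one row per guide and the columns
#' `sequence` (validated 30-mer), `gene_id`, `activity_score`,
#' `percent_peptide`, `amino_acid_cut_position` and `binary_label`.
#' Row order is preserved from the input everywhere in the package; ranks,
#' labels and cross-validation folds are all stable under it.
#'
#' @param sequence character vector of 30-mers.
#' @param gene_id character vector of target-gene identifiers.
#' @param activity_score numeric activity (higher = more active), NA allowed.
#' @param percent_peptide numeric in \[0, 100\] or NA.
#' @param amino_acid_cut_position non-negative numeric or NA.
#' @param binary_label 0/1 or NA.
#' @param provenance free-text description of where the guides came from.
#' @return a `guide_dataset` data frame.
#' @export
guide_dataset <- function(sequence, gene_id,
                          activity_score = NA_real_,
                          percent_peptide = NA_real_,
                          amino_acid_cut_position = NA_real_,
                          binary_label = NA_integer_,
                          provenance = "constructed in R") {
  sequence <- validate_guide(sequence)
  gene_id <- as.character(gene_id)
  if (length(gene_id) == 1L) gene_id <- rep(gene_id, length(sequence))
  if (any(is.na(gene_id) | !nzchar(gene_id))) {
    stop("every guide needs a non-empty gene_id", call. = FALSE)
  }
  ds <- data.frame(
    sequence = sequence,
    gene_id = gene_id,
    activity_score = rep_len(as.numeric(activity_score), length(sequence)),
    percent_peptide = rep_len(as.numeric(percent_peptide), length(sequence)),
    amino_acid_cut_position =
      rep_len(as.numeric(amino_acid_cut_position), length(sequence)),
    binary_label = rep_len(as.integer(binary_label), length(sequence)),
    stringsAsFactors = FALSE
  )
  attr(ds, "provenance") <- provenance
  class(ds) <- c("guide_dataset", "data.frame")
  ds
}

#' @export
print.guide_dataset <- function(x, ...) {
  cat(sprintf(
    "guide_dataset: %d guides, %d gene(s)%s\n",
    nrow(x), length(unique(x$gene_id)),
    if (all(is.na(x$binary_label))) "" else
      sprintf(", %d labeled positive", sum(x$binary_label == 1L, na.rm = TRUE))
  ))
  cat(sprintf("provenance: %s\n", attr(x, "provenance") %||% "unknown"))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a guide table from CSV
#'
#' Reads an Azimuth-style guide table (RFC-4180 CSV with a header row).
#' Column roles are resolved through `column_map`; any column not mapped to
#' a role is dropped, so assay bookkeeping columns (drug names, clone ids,
#' ...) never reach the model. Auxiliary covariates missing from the file
#' are recorded as `NA`, never as zero; imputation happens at featurization
#' time with training-set medians.
#'
#' @param path CSV file path.
#' @param column_map named list mapping roles (`sequence`, `gene_id`,
#'   `activity_score`, `percent_peptide`, `amino_acid_cut_position`) to
#'   header names; defaults match the Azimuth CSV dialect.
#' @param on_invalid `"error"` (fail fast, naming the offending row) or
#'   `"skip"` (drop invalid rows with a warning).
#' @param dedupe drop duplicate 30-mers, keeping the first occurrence?
#'   Off by default: replicate measurements of the same guide are real rows.
#' @return a [guide_dataset()].
#' @export
read_guide_table <- function(path, column_map = .default_column_map(),
                             on_invalid = c("error", "skip"),
                             dedupe = FALSE) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cmap <- utils::modifyList(.default_column_map(), as.list(column_map))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sequence", "gene_id", "activity_score")
  for (role in required) {
    if (!cmap[[role]] %in% names(raw)) {
      stop(sprintf(
        "column '%s' (role %s) not in header; available columns: %s",
        cmap[[role]], role, paste(names(raw), collapse = ", ")
      ), call. = FALSE)
    }
  }
  get_optional <- function(role) {
    if (cmap[[role]] %in% names(raw)) as.numeric(raw[[cmap[[role]]]])
    else rep(NA_real_, nrow(raw))
  }
  seqs <- toupper(as.character(raw[[cmap$sequence]]))
  valid <- nchar(seqs) == 30L & !grepl("[^ACGT]", seqs)
  if (!all(valid)) {
    rows <- which(!valid)
    if (on_invalid == "error") {
      stop(sprintf(
        "invalid guide sequence at row %d: '%s'",
        rows[1L], raw[[cmap$sequence]][rows[1L]]
      ), call. = FALSE)
    }
    warning(sprintf("skipping %d row(s) with invalid sequences (rows %s)",
                    length(rows), paste(utils::head(rows, 10L), collapse = ", ")),
            call. = FALSE)
  }
  keep <- which(valid)
  ds <- guide_dataset(
    sequence = seqs[keep],
    gene_id = as.character(raw[[cmap$gene_id]])[keep],
    activity_score = as.numeric(raw[[cmap$activity_score]])[keep],
    percent_peptide = get_optional("percent_peptide")[keep],
    amino_acid_cut_position = get_optional("amino_acid_cut_position")[keep],
    provenance = sprintf("read_guide_table('%s')", path)
  )
  if (dedupe) {
    ds <- ds[!duplicated(ds$sequence), , drop = FALSE]
    class(ds) <- c("guide_dataset", "data.frame")
  }
  ds
}

#' Write a guide dataset to CSV
#'
#' Emits the same dialect [read_guide_table()] reads with its default
#' `column_map`, so write-then-read round-trips exactly.
#'
#' @param dataset a [guide_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_guide_table <- function(dataset, path) {
  cmap <- .default_column_map()
  out <- data.frame(
    a = dataset$sequence, b = dataset$gene_id, c = dataset$activity_score,
    d = dataset$percent_peptide, e = dataset$amino_acid_cut_position,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- unlist(cmap[c("sequence", "gene_id", "activity_score",
                              "percent_peptide", "amino_acid_cut_position")])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read bare 30-mer sequences from FASTA
#'
#' Prediction-only input path: each record becomes a guide with
#' `gene_id` = the record id (up to the first whitespace) and all scores
#' and covariates missing.
#'
#' @param path FASTA file with at least one record.
#' @return a [guide_dataset()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("empty FASTA: no records found", call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  rec <- cumsum(hdr)
  seqs <- vapply(
    split(lines[!hdr], rec[!hdr]),
    function(x) paste(x, collapse = ""), character(1L)
  )
  if (length(seqs) != length(ids)) {
    stop("malformed FASTA: record without sequence lines", call. = FALSE)
  }
  guide_dataset(
    sequence = unname(seqs), gene_id = ids,
    provenance = sprintf("read_fasta('%s')", path)
  )
}

#' Derive binary activity labels by score rank
#'
#' The activity assays yield a continuous per-guide score; the binary
#' "active" truth used for ROC/PR/MCC evaluation marks the top fraction of
#' guides by score. With `grouping = "per_gene"` (the default) the fraction
#' is applied within each gene, matching gene-wise evaluation and an
#' overall positive rate of about the requested fraction. The per-group
#' positive count is `round(fraction * group size)` (round half up), ties
#' on score are broken by input row order, so labeling is deterministic
#' and idempotent.
#'
#' @param dataset a [guide_dataset()] with no missing `activity_score`.
#' @param positive_fraction fraction in (0, 1) labeled positive (default 0.2).
#' @param grouping `"per_gene"` or `"global"`.
#' @return the dataset with `binary_label` filled in.
#' @export
derive_binary_labels <- function(dataset, positive_fraction = 0.2,
                                 grouping = c("per_gene", "global")) {
  grouping <- match.arg(grouping)
  if (!is.numeric(positive_fraction) || length(positive_fraction) != 1L ||
      positive_fraction <= 0 || positive_fraction >= 1) {
    stop("`positive_fraction` must be a single number in (0, 1)", call. = FALSE)
  }
  if (anyNA(dataset$activity_score)) {
    stop("all guides need an activity_score to derive labels", call. = FALSE)
  }
  groups <- if (grouping == "per_gene") dataset$gene_id else
    rep("all", nrow(dataset))
  label <- integer(nrow(dataset))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n_pos <- floor(positive_fraction * length(idx) + 0.5)  # round half up
    if (n_pos > 0L) {
      # stable: order() is stable, so ties fall to the lower row index
      top <- idx[order(-dataset$activity_score[idx])][seq_len(n_pos)]
      label[top] <- 1L
    }
  }
  dataset$binary_label <- label
  dataset
}
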