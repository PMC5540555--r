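NUC <- c("A", "C", "G", "T")

#' Feature specification for the 9632-feature guide encoding
#'
#' With all defaults the encoding of one 30-mer has
#' 120 + 464 + 1792 + 6912 position-specific indicators (k = 1..4),
#' 340 position-independent counts (k = 1..4), minimum free energy and
#' specific heat of the transcribed guide, and the two assay covariates
#' (amino-acid cut position, percent peptide): 9632 columns in a fixed,
#' documented order.
#'
#' @param kmax_position_specific largest k for positional indicators (1..4).
#' @param kmax_position_independent largest k for k-mer counts (1..4).
#' @param include_thermodynamic include MFE and specific heat? Requires the
#'   ViennaRNA tools `RNAfold` and `RNAheat` on the PATH.
#' @param include_auxiliary include amino-acid cut position and percent
#'   peptide?
#' @param folding_temperature folding temperature in degrees Celsius.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(kmax_position_specific = 4L,
                         kmax_position_independent = 4L,
                         include_thermodynamic = TRUE,
                         include_auxiliary = TRUE,
                         folding_temperature = 37) {
  stopifnot(
    kmax_position_specific %in% 1:4,
    kmax_position_independent %in% 1:4,
    is.numeric(folding_temperature), length(folding_temperature) == 1L
  )
  structure(
    list(
      kmax_position_specific = as.integer(kmax_position_specific),
      kmax_position_independent = as.integer(kmax_position_independent),
      include_thermodynamic = isTRUE(include_thermodynamic),
      include_auxiliary = isTRUE(include_auxiliary),
      folding_temperature = as.numeric(folding_temperature)
    ),
    class = "feature_spec"
  )
}

#' Positional feature name
#'
#' Position-specific features are named `<KMER>_<start>` with a 1-based
#' start position in the 30-mer, e.g. `G_24` (a G at position 24) or
#' `GAGG_24` (GAGG starting at position 24). Position-independent count
#' features are the bare k-mer string.
#'
#' @param kmer k-mer over A/C/G/T, length 1..4.
#' @param start_position 1-based start, at most `31 - nchar(kmer)`.
#' @return the feature name string.
#' @examples
#' feature_name("G", 24)     # "G_24"
#' feature_name("GAGG", 24)  # "GAGG_24"
#' @export
feature_name <- function(kmer, start_position) {
  kmer <- toupper(kmer)
  if (grepl("[^ACGT]", kmer) || !nchar(kmer) %in% 1:4) {
    stop("`kmer` must be 1-4 characters over A/C/G/T", call. = FALSE)
  }
  start_position <- as.integer(start_position)
  if (start_position < 1L || start_position > 31L - nchar(kmer)) {
    stop(sprintf("start_position %d out of range for a %d-mer in a 30-mer",
                 start_position, nchar(kmer)), call. = FALSE)
  }
  paste0(kmer, "_", start_position)
}

# All k-mers of width k in lexicographic order (A < C < G < T).
all_kmers <- function(k) {
  if (k == 1L) return(NUC)
  grid <- do.call(expand.grid,
                  c(rep(list(NUC), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  do.call(paste0, rev(grid))
}

#' Feature names for a specification
#'
#' The fixed column order: position-specific blocks for k = 1..4 (position
#' ascending, k-mer lexicographic within a position), position-independent
#' blocks for k = 1..4 (k-mer lexicographic), then `mfe`, `specific_heat`,
#' then `amino_acid_cut_position`, `percent_peptide`.
#'
#' @param spec a [feature_spec()].
#' @return character vector of column names (length 9632 with defaults).
#' @export
feature_names <- function(spec = feature_spec()) {
  nm <- character(0)
  for (k in seq_len(spec$kmax_position_specific)) {
    kmers <- all_kmers(k)
    for (p in seq_len(31L - k)) nm <- c(nm, paste0(kmers, "_", p))
  }
  for (k in seq_len(spec$kmax_position_independent)) {
    nm <- c(nm, all_kmers(k))
  }
  if (spec$include_thermodynamic) nm <- c(nm, "mfe", "specific_heat")
  if (spec$include_auxiliary) {
    nm <- c(nm, "amino_acid_cut_position", "percent_peptide")
  }
  nm
}

# Integer codes 0..3 (A,C,G,T) for each position of each sequence;
# returns an n x 30 matrix.
encode_sequences <- function(sequences) {
  n <- length(sequences)
  codes <- matrix(0L, n, 30L)
  lookup <- integer(128L)
  lookup[utf8ToInt("A")] <- 0L; lookup[utf8ToInt("C")] <- 1L
  lookup[utf8ToInt("G")] <- 2L; lookup[utf8ToInt("T")] <- 3L
  for (i in seq_len(n)) codes[i, ] <- lookup[utf8ToInt(sequences[i])]
  codes
}

# n x (31-k) matrix of 1-based k-mer ranks at each start position.
kmer_ranks <- function(codes, k) {
  n_start <- 31L - k
  ranks <- codes[, seq_len(n_start), drop = FALSE] * 4L^(k - 1L)
  if (k > 1L) {
    for (j in 2:k) {
      ranks <- ranks +
        codes[, j:(j + n_start - 1L), drop = FALSE] * 4L^(k - j)
    }
  }
  ranks + 1L
}

#' Position-specific k-mer indicator features
#'
#' One binary column per (k-mer, start position) pair: 1 iff the sequence
#' carries that k-mer starting at that position. For width k there are
#' `(31 - k) * 4^k` columns of which exactly `31 - k` are 1.
#'
#' @param sequence one or more validated 30-mers.
#' @param k k-mer width in 1..4.
#' @return a named binary matrix with one row per sequence (a named vector
#'   for a single sequence).
#' @export
position_specific_features <- function(sequence, k) {
  k <- as.integer(k)
  if (!k %in% 1:4) stop("`k` must be in 1..4", call. = FALSE)
  sequence <- validate_guide(sequence)
  codes <- encode_sequences(sequence)
  n <- length(sequence)
  n_start <- 31L - k
  m <- matrix(0, n, n_start * 4L^k)
  ranks <- kmer_ranks(codes, k)
  cols <- sweep(ranks, 2L, (seq_len(n_start) - 1L) * 4L^k, "+")
  m[cbind(rep(seq_len(n), n_start), as.vector(cols))] <- 1
  kmers <- all_kmers(k)
  colnames(m) <- as.vector(vapply(
    seq_len(n_start), function(p) paste0(kmers, "_", p),
    character(4L^k)
  ))
  if (n == 1L) m[1L, ] else m
}

#' Position-independent k-mer count features
#'
#' One integer column per k-mer: the number of (overlapping) start
#' positions in the 30-mer carrying it. The `4^k` counts always sum to
#' `31 - k`.
#'
#' @inheritParams position_specific_features
#' @return a named count matrix (vector for a single sequence).
#' @export
position_independent_features <- function(sequence, k) {
  k <- as.integer(k)
  if (!k %in% 1:4) stop("`k` must be in 1..4", call. = FALSE)
  sequence <- validate_guide(sequence)
  codes <- encode_sequences(sequence)
  ranks <- kmer_ranks(codes, k)
  m <- t(apply(ranks, 1L, tabulate, nbins = 4L^k))
  colnames(m) <- all_kmers(k)
  if (length(sequence) == 1L) m[1L, ] else m
}

#' ViennaRNA folding engine adapter
#'
#' Wraps the `RNAfold` and `RNAheat` command-line tools. The engine
#' contract is a function `(sequences, temperature) -> data.frame(mfe,
#' specific_heat)`; any function with that signature can stand in (tests
#' use it to check the adapter against hand-run tool output).
#'
#' @return the engine function, or `NULL` when the tools are not on PATH.
#' @export
vienna_engine <- function() {
  if (Sys.which("RNAfold") == "" || Sys.which("RNAheat") == "") return(NULL)
  function(sequences, temperature) {
    rna <- chartr("T", "U", sequences)
    fa <- tempfile(fileext = ".fa")
    on.exit(unlink(fa), add = TRUE)
    writeLines(paste0(">s", seq_along(rna), "\n", rna), fa)
    fold <- system2("RNAfold",
                    c("--noPS", "-T", format(temperature),
                      paste0("--infile=", fa)),
                    stdout = TRUE)
    mfe_lines <- fold[seq(3L, length(fold), by = 3L)]
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", mfe_lines))
    # RNAheat hangs when Tmin == Tmax; ask for a 3-point window and keep
    # the middle row.
    heat <- system2("RNAheat",
                    c("--Tmin", format(temperature - 1),
                      "--Tmax", format(temperature + 1),
                      "--stepsize", "1"),
                    stdout = TRUE, stdin = fa)
    vals <- heat[!grepl("^>", heat)]
    tab <- utils::read.table(text = vals, col.names = c("temp", "heat"))
    sh <- tab$heat[abs(tab$temp - temperature) < 1e-6]
    data.frame(mfe = mfe, specific_heat = sh)
  }
}

#' Thermodynamic features of the transcribed guide
#'
#' Transcribes the 30-mer (T to U) and computes the minimum free energy
#' (kcal/mol, always <= 0) of its predicted secondary structure and the
#' specific heat (kcal/(mol K), >= 0) at the folding temperature. Both come
#' from the configured secondary-structure engine at its default
#' parameters.
#'
#' @param sequence one or more validated 30-mers (DNA alphabet).
#' @param temperature folding temperature in degrees Celsius.
#' @param engine an engine function as returned by [vienna_engine()];
#'   the default. When the engine is unavailable this is an error --
#'   thermodynamic columns are never silently zero-filled; disable them
#'   in the [feature_spec()] instead.
#' @return data frame with columns `mfe` and `specific_heat`.
#' @export
thermodynamic_features <- function(sequence, temperature = 37,
                                   engine = vienna_engine()) {
  sequence <- validate_guide(sequence)
  if (is.null(engine)) {
    stop(paste0(
      "no secondary-structure engine available (RNAfold/RNAheat not on ",
      "PATH); disable thermodynamic features in the feature_spec or ",
      "supply an engine"
    ), call. = FALSE)
  }
  out <- engine(sequence, temperature)
  stopifnot(nrow(out) == length(sequence))
  out
}

#' Featurize a guide dataset
#'
#' Builds the full feature matrix for a dataset: every guide becomes one
#' row over the fixed [feature_names()] column set. Missing auxiliary
#' covariates are imputed with the dataset median (or with externally
#' supplied values, e.g. the medians stored in a trained model); the
#' values used are attached as the `"imputation"` attribute.
#'
#' @param dataset a [guide_dataset()].
#' @param spec a [feature_spec()].
#' @param impute optional named list with `amino_acid_cut_position` and
#'   `percent_peptide` values to impute with; default: dataset medians.
#' @param engine secondary-structure engine, see [thermodynamic_features()].
#' @return numeric matrix, rows = guides, columns = [feature_names()],
#'   with attributes `spec` and `imputation`.
#' @export
featurize_dataset <- function(dataset, spec = feature_spec(),
                              impute = NULL, engine = vienna_engine()) {
  nm <- feature_names(spec)
  n <- nrow(dataset)
  if (n == 0L) {
    m <- matrix(numeric(0), 0L, length(nm), dimnames = list(NULL, nm))
    attr(m, "spec") <- spec
    return(m)
  }
  blocks <- list()
  for (k in seq_len(spec$kmax_position_specific)) {
    blocks[[length(blocks) + 1L]] <-
      position_specific_features(dataset$sequence, k)
  }
  for (k in seq_len(spec$kmax_position_independent)) {
    blocks[[length(blocks) + 1L]] <-
      position_independent_features(dataset$sequence, k)
  }
  if (spec$include_thermodynamic) {
    th <- thermodynamic_features(dataset$sequence,
                                 temperature = spec$folding_temperature,
                                 engine = engine)
    blocks[[length(blocks) + 1L]] <-
      matrix(c(th$mfe, th$specific_heat), n, 2L,
             dimnames = list(NULL, c("mfe", "specific_heat")))
  }
  imputation <- NULL
  if (spec$include_auxiliary) {
    aacp <- dataset$amino_acid_cut_position
    pp <- dataset$percent_peptide
    imp_aacp <- impute$amino_acid_cut_position %||%
      stats::median(aacp, na.rm = TRUE)
    imp_pp <- impute$percent_peptide %||% stats::median(pp, na.rm = TRUE)
    if (anyNA(aacp)) aacp[is.na(aacp)] <- imp_aacp
    if (anyNA(pp)) pp[is.na(pp)] <- imp_pp
    if (anyNA(aacp) || anyNA(pp)) {
      stop(paste0(
        "auxiliary covariates entirely missing and no imputation values ",
        "supplied; pass `impute` or disable auxiliary features"
      ), call. = FALSE)
    }
    imputation <- list(amino_acid_cut_position = imp_aacp,
                       percent_peptide = imp_pp)
    blocks[[length(blocks) + 1L]] <-
      matrix(c(aacp, pp), n, 2L,
             dimnames = list(NULL, c("amino_acid_cut_position",
                                     "percent_peptide")))
  }
  m <- do.call(cbind, blocks)
  stopifnot(identical(colnames(m), nm))
  rownames(m) <- NULL
  attr(m, "spec") <- spec
  attr(m, "imputation") <- imputation
  m
}

#' Write / read a feature matrix as CSV plus JSON manifest
#'
#' The CSV holds the matrix with feature names as header; the sidecar
#' `<path>.manifest.json` records the specification and a hash of the
#' column order so matrices, importance tables and models can be checked
#' for compatibility across runs.
#'
#' @param matrix a feature matrix from [featurize_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  spec <- attr(matrix, "spec")
  manifest <- list(
    n_rows = nrow(matrix),
    n_features = ncol(matrix),
    spec = unclass(spec),
    column_order_hash = column_hash(colnames(matrix))
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  manifest_path <- paste0(path, ".manifest.json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    if (!identical(manifest$column_order_hash, column_hash(colnames(m)))) {
      stop("feature matrix column order does not match its manifest",
           call. = FALSE)
    }
  }
  m
}

column_hash <- function(nm) {
  # order-sensitive 31-bit polynomial rolling hash of the concatenated names
  bytes <- utf8ToInt(paste(nm, collapse = "\x1f"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
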