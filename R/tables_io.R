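#' Construct a validated OTU table
#'
#' An OTU table is a non-negative integer count matrix with OTUs as rows and
#' samples as columns, plus a sample-to-environment labelling (for example
#' `"drainage"` and `"soil"`). All downstream stages of the pipeline take
#' this object.
#'
#' @param counts numeric matrix of non-negative integer counts, OTUs x
#'   samples, with unique row and column names.
#' @param environment named character vector mapping every sample id
#'   (column name of `counts`) to an environment label.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer storage) and `environment`.
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 0L, 3L, 1L), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("D1", "D2")))
#' ot <- otu_table(m, c(D1 = "drainage", D2 = "drainage"))
#' @export
otu_table <- function(counts, environment) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("OTU table needs OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicate OTU ids: %s",
           paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    .stopf("duplicate sample ids: %s",
           paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    .stopf("counts must be numeric with no missing values")
  if (any(counts < 0)) .stopf("negative count found: counts must be >= 0")
  if (any(counts != round(counts))) .stopf("non-integer count found")
  if (!is.character(environment) || is.null(names(environment)))
    .stopf("environment must be a named character vector (sample_id -> label)")
  missing_env <- setdiff(colnames(counts), names(environment))
  if (length(missing_env))
    .stopf("samples missing an environment label: %s", paste(missing_env, collapse = ", "))
  environment <- environment[colnames(counts)]
  tot <- colSums(counts)
  if (any(tot == 0))
    .stopf("sample(s) with zero total count: %s",
           paste(colnames(counts)[tot == 0], collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, environment = environment), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples\n", nrow(x$counts), ncol(x$counts)))
  env <- table(x$environment)
  cat("environments:", paste(sprintf("%s (n=%d)", names(env), as.integer(env)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Sample ids of an OTU table restricted to one environment
#' @param t an `otu_table`.
#' @param environment environment label.
#' @return character vector of sample ids.
#' @export
environment_samples <- function(t, environment) {
  stopifnot(inherits(t, "otu_table"))
  ids <- names(t$environment)[t$environment == environment]
  if (!length(ids)) .stopf("unknown environment '%s'", environment)
  ids
}

#' Construct a validated chemistry table
#'
#' @param values numeric matrix, samples x parameters, with sample ids as row
#'   names and parameter names as column names. No missing values.
#' @return object of class `chemistry_table` (a numeric matrix).
#' @export
chemistry_table <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("chemistry table needs sample row names and parameter column names")
  if (anyDuplicated(rownames(values))) .stopf("duplicate sample ids in chemistry table")
  if (anyDuplicated(colnames(values))) .stopf("duplicate parameter names in chemistry table")
  if (!is.numeric(values)) .stopf("chemistry values must be numeric")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    .stopf("missing chemistry value at sample '%s', parameter '%s'",
           rownames(values)[idx[1]], colnames(values)[idx[2]])
  }
  structure(values, class = c("chemistry_table", "matrix"))
}

#' The sixteen geochemical parameters measured in the motivating study
#'
#' Reference list of canonical parameter names (metals, pH and organic
#' matter) bundled for convenience; loaders accept any parameter set.
#'
#' @return character vector of length 16.
#' @export
canonical_chemistry_parameters <- function() {
  c("cadmium", "calcium", "lead", "copper", "chromium", "sulfur",
    "iron", "phosphorus", "magnesium", "manganese", "nickel",
    "potassium", "sodium", "zinc", "pH", "organic_matter")
}

.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

# "k__Bacteria; p__X; ...; g__Y" -> named rank vector, NA where absent
.parse_lineage <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  out <- stats::setNames(rep(NA_character_, length(.tax_ranks)), .tax_ranks)
  prefixes <- c(domain = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  for (p in parts) {
    hit <- which(startsWith(p, prefixes))
    if (length(hit) == 1) {
      val <- substring(p, 4)
      out[names(prefixes)[hit]] <- if (nzchar(val)) val else NA_character_
    }
  }
  # bare names without rank prefixes: fill ranks in order
  if (all(is.na(out)) && length(parts))
    out[seq_along(parts)] <- parts
  out
}

# Read a TSV, dropping "# ..." comment lines but keeping a "#OTU ID" header.
.read_tsv_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") | startsWith(lines, "#OTU ID")
  lines <- lines[keep]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopf("empty file: %s", path)
  utils::read.delim(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = "\t", check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' Read an OTU table from TSV
#'
#' The canonical on-disk layout follows the classic tab-separated OTU-table
#' convention: first column `#OTU ID`, one column per sample, and an optional
#' trailing `taxonomy` column holding lineage strings, which is split off
#' into a taxonomy map (attached as attribute `"taxonomy"`).
#'
#' @param path path to the TSV file.
#' @param env either a named character vector (sample id -> environment) or
#'   the path of a two-column TSV with header `sample_id<TAB>environment`.
#' @param orientation `"otus_as_rows"` (default, canonical) or
#'   `"samples_as_rows"` for transposed input.
#' @return a validated [otu_table], possibly with a `"taxonomy"` attribute
#'   (a data.frame as returned by [read_taxonomy]).
#' @export
read_otu_table <- function(path, env,
                           orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- .read_tsv_body(path)
  if (ncol(df) < 2) .stopf("OTU table '%s' has no sample columns", path)
  ids <- as.character(df[[1]])
  tax <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    lineages <- as.character(df[[ncol(df)]])
    df <- df[, -ncol(df), drop = FALSE]
    tax_mat <- t(vapply(lineages, .parse_lineage, character(length(.tax_ranks))))
    tax <- data.frame(otu_id = ids, tax_mat, row.names = NULL,
                      stringsAsFactors = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) .stopf("non-numeric count cell in '%s'", path)
  rownames(m) <- ids
  if (orientation == "samples_as_rows") {
    m <- t(m)
    if (!is.null(tax)) tax <- NULL  # taxonomy column only meaningful for OTU rows
  }
  if (is.character(env) && length(env) == 1 && is.null(names(env)))
    env <- read_env_map(env)
  ot <- otu_table(m, env)
  if (!is.null(tax)) attr(ot, "taxonomy") <- tax[match(rownames(ot$counts), tax$otu_id), ]
  ot
}

#' Read a sample-to-environment map
#' @param path two-column TSV with header `sample_id<TAB>environment`.
#' @return named character vector.
#' @export
read_env_map <- function(path) {
  df <- .read_tsv_body(path)
  if (ncol(df) < 2) .stopf("environment map '%s' needs two columns", path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a chemistry table from TSV
#'
#' @param path TSV with first column `sample_id` and one numeric column per
#'   parameter.
#' @param missing `"reject"` (default) errors on any missing value;
#'   `"impute_median"` replaces missing values with the per-parameter median.
#' @return a [chemistry_table].
#' @export
read_chemistry <- function(path, missing = c("reject", "impute_median")) {
  missing <- match.arg(missing)
  df <- .read_tsv_body(path)
  if (ncol(df) < 2) .stopf("chemistry table '%s' has no parameter columns", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & trimws(as.character(vals[[j]])) != "NA")
    if (length(bad))
      .stopf("non-numeric chemistry cell at row %d (sample '%s'), column '%s'",
             bad[1], ids[bad[1]], names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    if (missing == "reject") {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      .stopf("missing chemistry value at sample '%s', parameter '%s' (use missing = 'impute_median' to impute)",
             rownames(m)[idx[1]], colnames(m)[idx[2]])
    }
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) m[na, j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }
  chemistry_table(m)
}

#' Read a taxonomy map
#'
#' Accepts either a two-column TSV (`otu_id`, `taxonomy` lineage strings such
#' as `"k__Bacteria; p__X; ...; g__Y"`) or a TSV with explicit rank columns.
#' Unknown ranks are kept as `NA` placeholders.
#'
#' @param path TSV path.
#' @return data.frame with columns `otu_id`, `domain` ... `genus`.
#' @export
read_taxonomy <- function(path) {
  df <- .read_tsv_body(path)
  names(df)[1] <- "otu_id"
  if (ncol(df) == 2 && !all(.tax_ranks %in% names(df))) {
    tax_mat <- t(vapply(as.character(df[[2]]), .parse_lineage,
                        character(length(.tax_ranks))))
    df <- data.frame(otu_id = as.character(df$otu_id), tax_mat,
                     row.names = NULL, stringsAsFactors = FALSE)
  } else {
    for (r in .tax_ranks) if (!r %in% names(df)) df[[r]] <- NA_character_
    df <- df[, c("otu_id", .tax_ranks)]
    df$otu_id <- as.character(df$otu_id)
  }
  df
}

#' Convert counts to relative abundances
#'
#' Each sample (column) is divided by its total so columns sum to one. The
#' transformation is scale-invariant per sample: multiplying a sample's
#' counts by a positive constant leaves its relative-abundance column
#' unchanged.
#'
#' @param x an [otu_table] or a non-negative numeric matrix (OTUs x samples).
#' @return numeric matrix of the same shape with columns summing to 1;
#'   the environment labelling (if any) is carried in attribute
#'   `"environment"`.
#' @export
to_relative_abundance <- function(x) {
  env <- NULL
  if (inherits(x, "otu_table")) {
    env <- x$environment
    x <- x$counts
  }
  x <- as.matrix(x)
  tot <- colSums(x)
  if (any(tot <= 0))
    .stopf("sample(s) with zero total: %s",
           paste(colnames(x)[tot <= 0], collapse = ", "))
  out <- sweep(x, 2, tot, "/")
  storage.mode(out) <- "double"
  if (!is.null(env)) attr(out, "environment") <- env
  out
}

# ---- writing -------------------------------------------------------------

.write_header <- function(con, meta) {
  writeLines(sprintf("# minecore %s", .mc_version()), con)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
}

.write_df_tsv <- function(df, path, meta) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  .write_header(con, meta)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, .format_cell)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write a pipeline table to TSV
#'
#' All outputs are UTF-8 TSV with a `#`-prefixed comment header recording the
#' tool version and any metadata supplied in `meta` (typically the config
#' hash and seed). Writing is deterministic and round-trippable: re-reading
#' reproduces integer values exactly and reals to full double precision.
#'
#' @param x a table-like pipeline object ([otu_table], [chemistry_table],
#'   niche classification, correlation table, core result, or plain
#'   data.frame).
#' @param path output file path.
#' @param meta named list written into the comment header (e.g.
#'   `list(seed = 1)`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, meta = list()) UseMethod("write_table")

#' @export
write_table.data.frame <- function(x, path, meta = list()) {
  .write_df_tsv(x, path, meta)
}

#' @export
write_table.otu_table <- function(x, path, meta = list()) {
  tax <- attr(x, "taxonomy")
  df <- data.frame(`#OTU ID` = rownames(x$counts), as.data.frame(x$counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(tax)) {
    lineage <- apply(tax[, .tax_ranks, drop = FALSE], 1, function(r) {
      pre <- c("k__", "p__", "c__", "o__", "f__", "g__")
      paste0(pre, ifelse(is.na(r), "", r), collapse = "; ")
    })
    df$taxonomy <- lineage
  }
  .write_df_tsv(df, path, meta)
}

#' @export
write_table.chemistry_table <- function(x, path, meta = list()) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_df_tsv(df, path, meta)
}

#' Write a sample-to-environment map
#' @param env named character vector.
#' @param path output path.
#' @param meta header metadata, see [write_table].
#' @return `path`, invisibly.
#' @export
write_env_map <- function(env, path, meta = list()) {
  df <- data.frame(sample_id = names(env), environment = unname(env),
                   stringsAsFactors = FALSE)
  .write_df_tsv(df, path, meta)
}
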