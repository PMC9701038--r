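#' @keywords internal
"_PACKAGE"

OMICS_LAYERS <- c("mrna", "protein", "phospho", "cna", "cellscore")
OMICS_SCALES <- c("linear_nonneg", "log2", "zscore", "logratio")
VARIANT_CLASSES <- c("missense", "nonsense", "inframe", "frameshift", "other")

#' Construct a single-layer omics matrix
#'
#' An `omics_matrix` is the common currency of the pipeline: one molecular
#' layer as a features-by-samples real matrix with a declared layer and scale.
#' Missing values are allowed for the protein and phospho layers (mass-spec
#' dropout); a missing value is distinct from zero.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique rownames (feature IDs) and colnames (sample IDs).
#' @param layer one of `"mrna"`, `"protein"`, `"phospho"`, `"cna"`,
#'   `"cellscore"`.
#' @param scale one of `"linear_nonneg"`, `"log2"`, `"zscore"`, `"logratio"`.
#'   The `cna` layer must be on the `logratio` scale; `mrna`/`protein` on the
#'   `linear_nonneg` scale must be non-negative wherever observed.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer, scale) {
  layer <- match.arg(layer, OMICS_LAYERS)
  scale <- match.arg(scale, OMICS_SCALES)
  if (!is.matrix(values) || !is.numeric(values[1, 1][[1]]) && !all(is.na(values)))
    stop("'values' must be a numeric matrix")
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (layer == "cna" && scale != "logratio")
    stop("layer 'cna' requires scale 'logratio'")
  if (layer %in% c("mrna", "protein") && scale == "linear_nonneg" &&
      any(values < 0, na.rm = TRUE))
    stop("layer '", layer, "' on scale 'linear_nonneg' must be non-negative")
  structure(list(values = values, layer = layer, scale = scale),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: layer=%s scale=%s  %d features x %d samples (%.1f%% missing)\n",
              x$layer, x$scale, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

as_values <- function(x) if (inherits(x, "omics_matrix")) x$values else x

#' Read a feature-by-sample abundance matrix from TSV
#'
#' The file must have a header row of sample IDs and feature IDs in the first
#' column. Empty cells and the literal string `NA` become missing values
#' (distinct from zero). Non-numeric cells and duplicate feature IDs are
#' rejected with an error naming the offender.
#'
#' @param path TSV file path.
#' @inheritParams omics_matrix
#' @return an [omics_matrix].
#' @export
read_matrix <- function(path, layer, scale) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""),
                           comment.char = "#")
  if (ncol(raw) < 2) stop("matrix file needs a feature-ID column plus >= 1 sample column")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  omics_matrix(num, layer, scale)
}

#' Write an omics matrix to TSV
#'
#' Missing values are written as empty cells; `write_matrix` followed by
#' [read_matrix] with the same layer/scale is the identity.
#'
#' @param x an [omics_matrix] (or bare matrix).
#' @param path output file path.
#' @export
write_matrix <- function(x, path) {
  v <- as_values(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

CLINICAL_COLS <- c("sample_id", "patient_id", "tissue", "age", "sex",
                   "tnm_stage", "location", "diabetes", "metastasis",
                   "blood_glucose", "purity", "os_time", "os_event",
                   "dfs_time", "dfs_event")

#' Read a per-sample clinical table
#'
#' Validates the clinical schema: tissue in tumor/nat, at most one paired NAT
#' per patient, non-negative survival times and 0/1 event indicators.
#'
#' @param path TSV path with the clinical columns.
#' @return a `data.frame` of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLINICAL_COLS, names(df))
  if (length(missing_cols))
    stop("clinical table missing columns: ", paste(missing_cols, collapse = ", "))
  validate_clinical(df)
}

validate_clinical <- function(df) {
  if (!all(df$tissue %in% c("tumor", "nat")))
    stop("tissue must be 'tumor' or 'nat'")
  nat <- df[df$tissue == "nat", ]
  if (anyDuplicated(nat$patient_id))
    stop("a patient may have at most one paired NAT sample")
  tum <- df[df$tissue == "tumor", ]
  if (anyDuplicated(tum$patient_id))
    stop("a patient may have at most one tumor sample")
  for (col in c("os_time", "dfs_time"))
    if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " must be >= 0")
  for (col in c("os_event", "dfs_event"))
    if (!all(df[[col]] %in% c(0, 1, NA))) stop(col, " must be 0/1")
  if (any(df$purity < 0 | df$purity > 1, na.rm = TRUE))
    stop("purity must lie in [0, 1]")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' @export
#' @rdname read_clinical
write_clinical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

MAF_REQUIRED <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
                  "Reference_Allele", "Tumor_Seq_Allele2")

map_variant_class <- function(x) {
  out <- rep("other", length(x))
  out[grepl("^Missense", x, ignore.case = TRUE)] <- "missense"
  out[grepl("^Nonsense", x, ignore.case = TRUE)] <- "nonsense"
  out[grepl("^In_?Frame", x, ignore.case = TRUE)] <- "inframe"
  out[grepl("^Frame_?Shift", x, ignore.case = TRUE)] <- "frameshift"
  out[x %in% VARIANT_CLASSES] <- x[x %in% VARIANT_CLASSES]
  out
}

revcomp <- function(s) {
  vapply(s, function(x) {
    if (is.na(x)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize trinucleotide contexts to the pyrimidine-centred strand
#'
#' Single-base substitutions whose reference allele is a purine (A or G) are
#' reverse-complemented so that the centre base of the context is C or T, the
#' convention used by the 96-channel substitution catalog. Already-normalized
#' records are returned unchanged (the map is idempotent).
#'
#' @param context character vector of 3-mers (or NA).
#' @param ref,alt reference and alternate alleles.
#' @return list with normalized `context`, `ref`, `alt`.
#' @export
normalize_context <- function(context, ref, alt) {
  stopifnot(length(context) == length(ref), length(ref) == length(alt))
  flip <- !is.na(ref) & ref %in% c("A", "G") & !is.na(alt) &
    alt %in% c("A", "C", "G", "T")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  out_ctx <- context
  out_ctx[flip] <- revcomp(context[flip])
  list(context = out_ctx,
       ref = ifelse(flip, comp(ref), ref),
       alt = ifelse(flip, comp(alt), alt))
}

#' Read a MAF-like mutation table
#'
#' Requires the columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`, `Reference_Allele`, `Tumor_Seq_Allele2`, and
#' optionally `Trinucleotide_Context`. Variant classifications are mapped to
#' the 5-level class enum and SNV contexts are normalized to the
#' pyrimidine-centred strand.
#'
#' @param path TSV file path.
#' @return a `data.frame` of class `mutation_table` with columns `sample_id`,
#'   `gene`, `variant_class`, `ref_allele`, `alt_allele`,
#'   `trinucleotide_context`, `protein_change`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          comment.char = "#")
  missing_cols <- setdiff(MAF_REQUIRED, names(df))
  if (length(missing_cols))
    stop("MAF missing required columns: ", paste(missing_cols, collapse = ", "))
  ctx <- if ("Trinucleotide_Context" %in% names(df))
    as.character(df$Trinucleotide_Context) else rep(NA_character_, nrow(df))
  out <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    gene = as.character(df$Hugo_Symbol),
    variant_class = map_variant_class(as.character(df$Variant_Classification)),
    ref_allele = as.character(df$Reference_Allele),
    alt_allele = as.character(df$Tumor_Seq_Allele2),
    trinucleotide_context = ctx,
    protein_change = if ("Protein_Change" %in% names(df))
      as.character(df$Protein_Change) else rep(NA_character_, nrow(df)),
    stringsAsFactors = FALSE)
  norm <- normalize_context(out$trinucleotide_context, out$ref_allele,
                            out$alt_allele)
  out$trinucleotide_context <- norm$context
  out$ref_allele <- norm$ref
  out$alt_allele <- norm$alt
  bad <- !is.na(out$trinucleotide_context) &
    !substr(out$trinucleotide_context, 2, 2) %in% c("C", "T")
  if (any(bad))
    stop("contexts remain purine-centred after normalization (non-SNV ref?): ",
         paste(utils::head(out$trinucleotide_context[bad]), collapse = ", "))
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' @export
#' @rdname read_maf
write_maf <- function(mut, path) {
  df <- data.frame(Hugo_Symbol = mut$gene,
                   Tumor_Sample_Barcode = mut$sample_id,
                   Variant_Classification = mut$variant_class,
                   Reference_Allele = mut$ref_allele,
                   Tumor_Seq_Allele2 = mut$alt_allele,
                   Trinucleotide_Context = mut$trinucleotide_context,
                   Protein_Change = mut$protein_change,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Sets with zero members are rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors, class `gene_set_collection`;
#'   descriptions kept in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- lengths(sets) == 0
  if (any(empty)) stop("gene set(s) with zero members: ",
                       paste(nm[empty], collapse = ", "))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
#' @rdname read_gmt
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(seq_along(sets), function(i) {
    d <- if (!is.null(desc)) desc[[names(sets)[i]]] else ""
    paste(c(names(sets)[i], d, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

PHOSPHOSITE_RE <- "^([A-Za-z0-9.-]+)_p([STY])([0-9]+)$"

#' Parse phosphosite identifiers of the form GENE_pS123
#'
#' @param ids character vector of site IDs.
#' @return data.frame with `site`, `gene`, `residue`, `position`.
#' @export
parse_phosphosite <- function(ids) {
  ok <- grepl(PHOSPHOSITE_RE, ids)
  if (!all(ok))
    stop("malformed phosphosite ID(s): ", paste(ids[!ok], collapse = ", "),
         " (expected GENE_p[STY]<position>)")
  data.frame(site = ids,
             gene = sub(PHOSPHOSITE_RE, "\\1", ids),
             residue = sub(PHOSPHOSITE_RE, "\\2", ids),
             position = as.integer(sub(PHOSPHOSITE_RE, "\\3", ids)),
             stringsAsFactors = FALSE)
}

#' Read a kinase-to-substrate-site map
#'
#' Two-column TSV (`kinase`, `site`), one substrate phosphosite per row; site
#' IDs must parse as `GENE_p[STY]<position>`.
#'
#' @param path TSV path.
#' @return named list (kinase -> character vector of site IDs), class
#'   `kinase_substrate_map`.
#' @export
read_ks_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("kinase-substrate map needs two columns (kinase, site)")
  names(df)[1:2] <- c("kinase", "site")
  parse_phosphosite(df$site)  # validates
  m <- split(df$site, df$kinase)
  m <- lapply(m, unique)
  class(m) <- "kinase_substrate_map"
  m
}

#' @export
#' @rdname read_ks_map
write_ks_map <- function(map, path) {
  df <- data.frame(kinase = rep(names(map), lengths(map)),
                   site = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The canonical 96 trinucleotide substitution channels
#'
#' Six pyrimidine-centred substitution types (C>A, C>G, C>T, T>A, T>C, T>G),
#' each with 16 flanking contexts in alphabetical order, giving labels such as
#' `"A[C>A]A"`. This fixed ordering makes cosine matching against reference
#' catalogs unambiguous.
#'
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", s, "]", r))))
  }))
}

#' Map (context, ref, alt) triples to channel labels
#' @param context pyrimidine-centred 3-mers.
#' @param ref,alt alleles (ref must match the context centre).
#' @return channel labels (NA where not a contextful SNV).
#' @export
sbs_channel_of <- function(context, ref, alt) {
  ok <- !is.na(context) & nchar(context) == 3 & !is.na(ref) & !is.na(alt) &
    ref %in% c("C", "T") & alt %in% c("A", "C", "G", "T") & ref != alt &
    substr(context, 2, 2) == ref
  out <- rep(NA_character_, length(context))
  out[ok] <- paste0(substr(context[ok], 1, 1), "[", ref[ok], ">", alt[ok], "]",
                    substr(context[ok], 3, 3))
  out[!out %in% sbs_channels()] <- NA
  out
}
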