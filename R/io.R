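# Readers and writers for the tabular inputs of the scoring pipeline:
# variant annotations, drug-gene maps, drug status labels, binned count
# tables, and multi-sample VCF genotype carriage.

#' @importFrom utils read.table write.table packageVersion
NULL

# All TSV inputs: UTF-8, mandatory header, "#" comment lines skipped.
.read_tsv <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty ", what, " file: ", path, call. = FALSE)
  df
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Build a variant key string
#'
#' Variants are identified exactly by chromosome, 1-based position, reference
#' allele and one alternate allele; multi-allelic records must be split into
#' one key per alternate allele before keys are formed.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref Reference allele(s).
#' @param alt Single alternate allele(s).
#' @return Character vector of keys, `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read a variant annotation table
#'
#' Reads a TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, `sift`. Rows whose consequence is not `nonsynonymous`, or
#' whose SIFT score is missing, are dropped with a counted warning; a SIFT
#' score outside \[0, 1\] or a non-numeric value is an error naming the
#' offending row. Gene symbols are whitespace-trimmed and matched
#' case-sensitively downstream; no alias resolution is attempted.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame of class `variant_annotation` with columns `chrom`,
#'   `pos` (integer), `ref`, `alt`, `gene`, `consequence`, `sift` (numeric)
#'   and `key`; attribute `n_dropped` counts the filtered rows.
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path, "annotation")
  .require_columns(df, c("chrom", "pos", "ref", "alt", "gene",
                         "consequence", "sift"), path)
  n_in <- nrow(df)
  # line numbers in the original file (header = line 1, no comment lines
  # assumed interleaved with data for reporting purposes)
  lineno <- seq_len(n_in) + 1L

  sift_chr <- trimws(df$sift)
  sift <- suppressWarnings(as.numeric(sift_chr))
  bad_num <- !is.na(sift_chr) & nzchar(sift_chr) &
    toupper(sift_chr) != "NA" & is.na(sift)
  if (any(bad_num))
    stop("non-numeric sift value at line ", lineno[which(bad_num)[1L]],
         ": '", sift_chr[which(bad_num)[1L]], "'", call. = FALSE)
  out_of_range <- !is.na(sift) & (sift < 0 | sift > 1)
  if (any(out_of_range))
    stop("sift score outside [0,1] at line ", lineno[which(out_of_range)[1L]],
         ": ", sift[which(out_of_range)[1L]], call. = FALSE)

  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos) || any(pos < 1L))
    stop("pos must be a positive integer (line ",
         lineno[which(is.na(pos) | pos < 1L)[1L]], ")", call. = FALSE)
  gene <- trimws(df$gene)
  if (any(!nzchar(gene)))
    stop("empty gene symbol at line ", lineno[which(!nzchar(gene))[1L]],
         call. = FALSE)
  if (any(grepl(",", df$alt, fixed = TRUE)))
    stop("multi-allelic alt in annotation at line ",
         lineno[which(grepl(",", df$alt, fixed = TRUE))[1L]],
         "; split records before annotating", call. = FALSE)
  if (any(df$ref == df$alt))
    stop("ref equals alt at line ", lineno[which(df$ref == df$alt)[1L]],
         call. = FALSE)

  keep <- trimws(df$consequence) == "nonsynonymous" & !is.na(sift)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(n_dropped, " annotation row(s) dropped (non-nonsynonymous ",
            "consequence or missing sift)", call. = FALSE)

  ann <- data.frame(chrom = df$chrom[keep], pos = pos[keep],
                    ref = df$ref[keep], alt = df$alt[keep],
                    gene = gene[keep],
                    consequence = trimws(df$consequence)[keep],
                    sift = sift[keep], stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  structure(ann, n_dropped = n_dropped,
            class = c("variant_annotation", "data.frame"))
}

#' Read genotype carriage from a multi-sample VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) and returns, for the variants
#' present in `annotations`, a boolean individual-by-variant carriage matrix:
#' `TRUE` iff the individual carries at least one copy of that alternate
#' allele. Multi-allelic records are split into one column per alternate
#' allele. Missing genotypes (`./.`) count as non-carriage and are tallied.
#' Phasing and zygosity are ignored: carriage is boolean.
#'
#' @param path Path to a multi-sample VCF (`.vcf` or `.vcf.gz`).
#' @param annotations A `variant_annotation` data frame; only its variants
#'   are retained.
#' @return An object of class `genotype_carriage`: a list with `individuals`,
#'   `variants` (data frame with `chrom`, `pos`, `ref`, `alt`, `key`),
#'   `carriage` (logical matrix, individuals x variants, variant keys as
#'   column names) and `n_missing` (count of missing genotype cells).
#' @export
read_vcf_carriage <- function(path, annotations) {
  stopifnot(inherits(annotations, "variant_annotation"))
  if (nrow(annotations) == 0L)
    stop("annotations are empty", call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed VCF '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF '", path, "' has no sample genotype columns", call. = FALSE)
  individuals <- colnames(gt)
  if (anyDuplicated(individuals))
    stop("duplicate individual ids in VCF: ",
         individuals[duplicated(individuals)][1L], call. = FALSE)

  wanted <- unique(annotations$key)
  rec <- list()
  n_missing <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    gts <- gt[i, ]
    alleles <- strsplit(ifelse(is.na(gts), ".", gts), "[/|]")
    for (a in seq_along(alts)) {
      key <- variant_key(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"],
                         alts[a])
      if (!key %in% wanted) next
      target <- as.character(a)
      carried <- vapply(alleles, function(x) any(x == target), logical(1L))
      miss <- vapply(alleles, function(x) all(x %in% c(".", "")), logical(1L))
      n_missing <- n_missing + sum(miss)
      rec[[key]] <- list(chrom = fix[i, "CHROM"],
                         pos = as.integer(fix[i, "POS"]),
                         ref = fix[i, "REF"], alt = alts[a],
                         carried = carried)
    }
  }
  if (length(rec) == 0L)
    stop("empty intersection: no VCF variant matches the annotations",
         call. = FALSE)
  variants <- data.frame(
    chrom = vapply(rec, `[[`, character(1L), "chrom"),
    pos = vapply(rec, `[[`, integer(1L), "pos"),
    ref = vapply(rec, `[[`, character(1L), "ref"),
    alt = vapply(rec, `[[`, character(1L), "alt"),
    key = names(rec), row.names = NULL, stringsAsFactors = FALSE)
  carriage <- do.call(cbind, lapply(rec, `[[`, "carried"))
  dimnames(carriage) <- list(individuals, names(rec))
  if (n_missing > 0L)
    message(n_missing, " missing genotype(s) treated as non-carriage")
  structure(list(individuals = individuals, variants = variants,
                 carriage = carriage, n_missing = n_missing),
            class = "genotype_carriage")
}

#' @export
print.genotype_carriage <- function(x, ...) {
  cat("Genotype carriage:", length(x$individuals), "individuals x",
      nrow(x$variants), "variants;",
      sum(x$carriage), "carried cells;",
      x$n_missing, "missing genotypes treated as non-carriage\n")
  invisible(x)
}

#' Construct a drug-gene map with an inclusion filter
#'
#' @param pairs Data frame with columns `drug_id`, `gene` and optionally
#'   `role` (one of `target`, `enzyme`, `carrier`, `transporter`).
#' @param min_genes Minimum number of distinct genes a drug must have to be
#'   included (default 5).
#' @return Object of class `drug_gene_map`: list with `gene_sets` (named list
#'   of gene character vectors, included drugs only), `pairs` (the full
#'   deduplicated table), `min_genes`, `n_excluded`.
#' @export
drug_gene_map <- function(pairs, min_genes = 5L) {
  stopifnot(is.data.frame(pairs), all(c("drug_id", "gene") %in% names(pairs)))
  min_genes <- as.integer(min_genes)
  if (is.na(min_genes) || min_genes < 1L)
    stop("min_genes must be >= 1", call. = FALSE)
  pairs$drug_id <- trimws(pairs$drug_id)
  pairs$gene <- trimws(pairs$gene)
  if (any(!nzchar(pairs$gene)) || any(!nzchar(pairs$drug_id)))
    stop("empty drug_id or gene symbol in drug-gene map", call. = FALSE)
  if ("role" %in% names(pairs)) {
    role <- trimws(pairs$role)
    ok <- role %in% c("target", "enzyme", "carrier", "transporter") |
      !nzchar(role) | is.na(role)
    if (!all(ok))
      stop("unknown role '", role[!ok][1L],
           "' (expected target/enzyme/carrier/transporter)", call. = FALSE)
  }
  dup <- duplicated(pairs[c("drug_id", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (drug, gene) pair(s) removed", call. = FALSE)
    pairs <- pairs[!dup, , drop = FALSE]
  }
  sets <- split(pairs$gene, pairs$drug_id)
  keep <- vapply(sets, function(g) length(unique(g)) >= min_genes, logical(1L))
  structure(list(gene_sets = lapply(sets[keep], unique),
                 pairs = pairs, min_genes = min_genes,
                 n_excluded = sum(!keep)),
            class = "drug_gene_map")
}

#' Read a drug-gene map TSV
#'
#' TSV columns: `drug_id`, `gene`, optional `role`. Drugs with fewer than
#' `min_genes` distinct genes are excluded (the count is stored on the
#' returned object); duplicate pairs are removed with a warning.
#'
#' @inheritParams drug_gene_map
#' @param path Path to the TSV.
#' @return A [drug_gene_map()] object.
#' @export
read_drug_gene_map <- function(path, min_genes = 5L) {
  df <- .read_tsv(path, "drug-gene map")
  .require_columns(df, c("drug_id", "gene"), path)
  drug_gene_map(df, min_genes = min_genes)
}

#' @export
print.drug_gene_map <- function(x, ...) {
  cat("Drug-gene map:", length(x$gene_sets), "drugs included (>=",
      x$min_genes, "genes);", x$n_excluded, "excluded;",
      length(unique(unlist(x$gene_sets))), "distinct genes\n")
  invisible(x)
}

.status_flags <- c("withdrawn_UN", "withdrawn_EMA", "withdrawn_DrugBank",
                   "precaution_Beers", "precaution_FDA")

#' Read drug status labels
#'
#' TSV columns: `drug_id` plus the five boolean flags `withdrawn_UN`,
#' `withdrawn_EMA`, `withdrawn_DrugBank`, `precaution_Beers`,
#' `precaution_FDA` (accepted encodings: TRUE/FALSE, 1/0). A drug is
#' "withdrawn" iff any withdrawn flag is set, and "other" iff all five flags
#' are clear; flags may overlap (a withdrawn drug can also be precautionary).
#'
#' @param path Path to the TSV.
#' @return Data frame of class `drug_status` with `drug_id`, the five logical
#'   flag columns, and derived logicals `withdrawn` and `other`.
#' @export
read_drug_status <- function(path) {
  df <- .read_tsv(path, "drug status")
  .require_columns(df, c("drug_id", .status_flags), path)
  out <- data.frame(drug_id = trimws(df$drug_id), stringsAsFactors = FALSE)
  for (fl in .status_flags) {
    v <- toupper(trimws(df[[fl]]))
    parsed <- v %in% c("TRUE", "T", "1")
    bad <- !v %in% c("TRUE", "T", "1", "FALSE", "F", "0")
    if (any(bad))
      stop("unparseable boolean '", df[[fl]][bad][1L], "' in column ", fl,
           call. = FALSE)
    out[[fl]] <- parsed
  }
  if (anyDuplicated(out$drug_id))
    stop("duplicate drug_id in status table: ",
         out$drug_id[duplicated(out$drug_id)][1L], call. = FALSE)
  out$withdrawn <- out$withdrawn_UN | out$withdrawn_EMA | out$withdrawn_DrugBank
  out$other <- !out$withdrawn & !out$precaution_Beers & !out$precaution_FDA
  structure(out, class = c("drug_status", "data.frame"))
}

#' Read a binned count table
#'
#' TSV layout: first column holds row labels, the remaining columns hold
#' per-bin nonnegative integer counts; one row (by default the last, or the
#' one named by `totals_row`) holds the per-bin totals. Event counts must not
#' exceed the totals in any bin.
#'
#' @param path Path to the TSV.
#' @param totals_row Label of the totals row; default `NULL` takes the last
#'   row.
#' @return Object of class `binned_counts`: list with `bins` (labels),
#'   `events` (integer matrix, one row per event series, bins as columns) and
#'   `totals` (integer vector).
#' @export
read_binned_counts <- function(path, totals_row = NULL) {
  df <- .read_tsv(path, "binned count")
  if (ncol(df) < 3L)
    stop("binned count table needs a label column and >= 2 bins", call. = FALSE)
  labels <- df[[1L]]
  counts <- as.matrix(df[, -1L, drop = FALSE])
  mode(counts) <- "numeric"
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  rownames(counts) <- labels
  ti <- if (is.null(totals_row)) nrow(counts) else match(totals_row, labels)
  if (is.na(ti)) stop("totals row '", totals_row, "' not found", call. = FALSE)
  totals <- counts[ti, ]
  events <- counts[-ti, , drop = FALSE]
  binned_counts(bins = colnames(counts), events = events, totals = totals)
}

#' Construct a binned count table
#'
#' @param bins Ordered bin labels.
#' @param events Integer matrix of event counts (rows = series, columns =
#'   bins); may have zero rows.
#' @param totals Integer vector of per-bin totals.
#' @return Object of class `binned_counts`.
#' @export
binned_counts <- function(bins, events, totals) {
  events <- as.matrix(events)
  if (nrow(events) > 0L && ncol(events) != length(totals))
    stop("events and totals disagree on the number of bins", call. = FALSE)
  if (length(bins) != length(totals))
    stop("bin labels and totals disagree in length", call. = FALSE)
  if (any(totals < 0) || (nrow(events) > 0L && any(events < 0)))
    stop("counts must be nonnegative", call. = FALSE)
  if (nrow(events) > 0L) {
    over <- which(t(events) > totals, arr.ind = TRUE)
    if (length(over) > 0L)
      stop("event count exceeds total in bin '", bins[over[1L, 1L]], "' (row '",
           rownames(events)[over[1L, 2L]], "')", call. = FALSE)
  }
  colnames(events) <- bins
  names(totals) <- bins
  structure(list(bins = bins, events = events, totals = totals),
            class = "binned_counts")
}

#' Write a binned count table
#'
#' Inverse of [read_binned_counts()]: writing then re-reading reproduces the
#' same integers.
#'
#' @param x A `binned_counts` object.
#' @param path Output path.
#' @param totals_label Label for the totals row (default "Total").
#' @param meta Optional named list written as `# key=value` comment headers.
#' @export
write_binned_counts <- function(x, path, totals_label = "Total", meta = NULL) {
  stopifnot(inherits(x, "binned_counts"))
  m <- rbind(x$events, matrix(x$totals, nrow = 1L,
                              dimnames = list(totals_label, x$bins)))
  df <- data.frame(row = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, meta = meta)
  invisible(path)
}

#' @export
print.binned_counts <- function(x, ...) {
  cat("Binned counts:", nrow(x$events), "event row(s) over",
      length(x$bins), "bins (totals sum ", sum(x$totals), ")\n", sep = "")
  invisible(x)
}

# TSV writer with auditable "# key=value" comment headers.
.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pgxsafety %s",
                     as.character(utils::packageVersion("pgxsafety"))), con)
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, as.character(meta[[k]])), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
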