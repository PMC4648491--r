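# SCNA x GWAS scanner: intersect recurrent somatic copy-number
# alteration peak regions with cancer-associated GWAS SNPs and flag loci
# where the SNP-associated cancer type matches the tumor type of the SCNA.

# split a "a; b; c" or "a, b" list cell into trimmed non-empty tokens
#' @keywords internal
#' @noRd
split_list_field <- function(x, sep = "[;,]") {
  out <- trimws(strsplit(as.character(x %||% ""), sep)[[1]])
  out[nzchar(out)]
}

#' @keywords internal
#' @noRd
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Construct SCNA peak-region records
#'
#' Validates a GISTIC-style table of recurrent SCNA peaks. Coordinates are
#' 1-based inclusive (hg19-style as printed in pan-cancer peak tables);
#' use [read_bed_regions()] for 0-based half-open BED input.
#'
#' @param df `data.frame` with columns `peak_name`, `cytoband`, `chrom`,
#'   `start`, `end`, `scna_type` (`"amplification"`/`"deletion"`),
#'   `peak_genes` (semicolon/comma list), `tumor_types` (comma list of
#'   controlled codes, e.g. BLCA).
#' @param genome_build declared build label (default `"hg19"`).
#' @return The validated `data.frame` with class `"scna_regions"` and a
#'   `genome_build` attribute.
#' @export
scna_regions <- function(df, genome_build = "hg19") {
  check_columns(df, c("peak_name", "cytoband", "chrom", "start", "end",
                      "scna_type", "peak_genes", "tumor_types"),
                file = "regions")
  if (any(df$start > df$end))
    abort_validation("region start must be <= end")
  bad <- setdiff(unique(df$scna_type), c("amplification", "deletion"))
  if (length(bad))
    abort_validation(sprintf("invalid scna_type: %s", paste(bad, collapse = ", ")))
  if (any(!nzchar(trimws(df$tumor_types))))
    abort_validation("every region needs a non-empty tumor_types list")
  df$chrom <- norm_chrom(df$chrom)
  attr(df, "genome_build") <- genome_build
  class(df) <- c("scna_regions", class(df))
  df
}

#' Construct GWAS-catalog SNP records
#'
#' @param df `data.frame` with columns `rsid`, `chrom`, `pos`, `trait`,
#'   `mapped_genes` (comma/semicolon list, may be empty).
#' @param genome_build declared build label (default `"hg19"`).
#' @return Validated `data.frame` with class `"gwas_snps"`.
#' @export
gwas_snps <- function(df, genome_build = "hg19") {
  check_columns(df, c("rsid", "chrom", "pos", "trait", "mapped_genes"),
                file = "snps")
  if (any(df$pos <= 0))
    abort_validation("SNP positions must be positive 1-based coordinates")
  df$chrom <- norm_chrom(df$chrom)
  attr(df, "genome_build") <- genome_build
  class(df) <- c("gwas_snps", class(df))
  df
}

#' Read an NHGRI-EBI GWAS-catalog-style TSV
#'
#' Consumes the catalog dialect (columns `SNPS`, `CHR_ID`, `CHR_POS`,
#' `DISEASE/TRAIT`, `MAPPED_GENE`). Rows with missing or non-numeric
#' positions, or multi-SNP haplotype entries (several rsids in `SNPS`),
#' are skipped with a message reporting the count.
#'
#' @param path TSV file path.
#' @param genome_build declared build label.
#' @return A [gwas_snps()] table.
#' @export
read_gwas_catalog <- function(path, genome_build = "hg19") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  check_columns(df, c("SNPS", "CHR_ID", "CHR_POS", "DISEASE/TRAIT",
                      "MAPPED_GENE"), file = path)
  pos <- suppressWarnings(as.numeric(df$CHR_POS))
  multi <- grepl("[;,x]", df$SNPS) | grepl("rs[0-9]+\\s+rs", df$SNPS)
  keep <- !is.na(pos) & pos > 0 & !multi & nzchar(df$CHR_ID)
  if (any(!keep))
    message(sprintf("read_gwas_catalog: skipped %d row(s) with missing positions or multi-SNP haplotypes",
                    sum(!keep)))
  gwas_snps(data.frame(
    rsid = df$SNPS[keep], chrom = df$CHR_ID[keep], pos = pos[keep],
    trait = df$`DISEASE/TRAIT`[keep],
    mapped_genes = gsub(" - ", ",", df$MAPPED_GENE[keep]),
    stringsAsFactors = FALSE
  ), genome_build = genome_build)
}

#' Read SCNA peak regions from a headered TSV
#'
#' @param path TSV with the [scna_regions()] columns.
#' @param genome_build declared build label.
#' @return A [scna_regions()] table.
#' @export
read_scna_regions <- function(path, genome_build = "hg19") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  scna_regions(df, genome_build = genome_build)
}

#' Read SCNA peak regions from BED
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' inclusive convention at the reader boundary. BED columns 4-6 are taken
#' as `peak_name`, `scna_type`, `tumor_types` (comma list); `peak_genes`
#' may follow as column 7.
#'
#' @param path BED file path.
#' @param genome_build declared build label.
#' @return A [scna_regions()] table.
#' @export
read_bed_regions <- function(path, genome_build = "hg19") {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    abort_validation("BED regions need >= 6 columns: chrom, start, end, name, scna_type, tumor_types")
  scna_regions(data.frame(
    peak_name = df[[4]], cytoband = NA_character_, chrom = df[[1]],
    start = df[[2]] + 1L, end = df[[3]], scna_type = df[[5]],
    peak_genes = if (ncol(df) >= 7) df[[7]] else "",
    tumor_types = df[[6]], stringsAsFactors = FALSE
  ), genome_build = genome_build)
}

#' Intersect SCNA regions with GWAS SNPs
#'
#' A SNP joins a region iff its position lies within the peak interval
#' (same chromosome, inclusive bounds) or it maps to a gene listed for the
#' peak. Regions gathering no SNPs are omitted.
#'
#' @param regions a [scna_regions()] table.
#' @param snps a [gwas_snps()] table.
#' @return A list of `"pai_candidate"` objects, each with `region`
#'   (one-row `data.frame`), `snps` (`data.frame`), `matched = NA` and
#'   empty `matched_types` (filled by [match_cancer_types()]).
#' @export
overlap_snps <- function(regions, snps) {
  if (!inherits(regions, "scna_regions")) regions <- scna_regions(regions)
  if (!inherits(snps, "gwas_snps")) snps <- gwas_snps(snps)
  rb <- attr(regions, "genome_build")
  sb <- attr(snps, "genome_build")
  if (!is.null(rb) && !is.null(sb) && !identical(rb, sb))
    abort_validation(sprintf("genome build mismatch: regions are %s, SNPs are %s", rb, sb))

  gr_regions <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
  gr_snps <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_regions)
  by_pos <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))

  snp_genes <- lapply(snps$mapped_genes, split_list_field)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    pos_idx <- by_pos[[as.character(i)]] %||% integer(0)
    genes <- split_list_field(regions$peak_genes[i])
    gene_idx <- if (length(genes))
      which(vapply(snp_genes, function(g) length(intersect(g, genes)) > 0,
                   logical(1)))
    else integer(0)
    idx <- sort(unique(c(pos_idx, gene_idx)))
    if (!length(idx)) next
    out[[length(out) + 1L]] <- structure(list(
      region = regions[i, , drop = FALSE],
      snps = snps[idx, , drop = FALSE],
      matched = NA, matched_types = character(0)
    ), class = "pai_candidate")
  }
  out
}

#' Load the cancer-type vocabulary
#'
#' A two-column TSV mapping trait phrases (lower-cased for matching) to
#' controlled tumor-type codes (comma lists). The packaged default covers
#' the phrases appearing in the shipped SCNA fixture.
#'
#' @param path TSV path; default is the packaged vocabulary.
#' @return `data.frame` with columns `phrase`, `codes`.
#' @export
load_vocab <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cancer_type_vocab.tsv",
                                package = "smartddpcr")
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(v, c("phrase", "codes"), file = path)
  v$phrase <- tolower(trimws(v$phrase))
  v
}

#' Map trait phrases to tumor-type codes
#'
#' @param traits character vector of trait phrases.
#' @param vocab a [load_vocab()] table.
#' @return A list (per input phrase) of code vectors; unmapped phrases map
#'   to `character(0)` and are reported via a warning, never dropped
#'   silently.
#' @export
map_traits <- function(traits, vocab) {
  key <- tolower(trimws(traits))
  idx <- match(key, vocab$phrase)
  unmapped <- unique(traits[is.na(idx) & nzchar(key)])
  if (length(unmapped))
    warning(sprintf("unmapped trait phrase(s): %s",
                    paste(unmapped, collapse = "; ")), call. = FALSE)
  lapply(seq_along(key), function(i) {
    if (is.na(idx[i])) character(0)
    else split_list_field(vocab$codes[idx[i]])
  })
}

#' Match SNP-associated cancer types against SCNA tumor types
#'
#' Fills `matched_types` with the intersection of the region's SCNA tumor
#' types and the union of cancer-type codes mapped from the overlapping
#' SNPs' traits (each trait cell may hold a semicolon list of phrases);
#' `matched` is `TRUE` iff that intersection is non-empty.
#'
#' @param cand a `"pai_candidate"` (from [overlap_snps()] or
#'   [table2_candidates()]).
#' @param vocab a [load_vocab()] table.
#' @return The candidate with `matched` and `matched_types` set.
#' @export
match_cancer_types <- function(cand, vocab = load_vocab()) {
  stopifnot(inherits(cand, "pai_candidate"))
  phrases <- unlist(lapply(cand$snps$trait, split_list_field, sep = ";"))
  snp_codes <- unique(unlist(map_traits(phrases, vocab)))
  region_codes <- split_list_field(cand$region$tumor_types)
  cand$matched_types <- sort(intersect(region_codes, snp_codes))
  cand$matched <- length(cand$matched_types) > 0
  cand
}

#' Summarize matched PAI candidates
#'
#' Counts matched loci overall, by SCNA type, per tumor-type code, and
#' (when a code-to-group table is supplied) per reporting group such as
#' "lung" spanning both lung adenocarcinoma and squamous codes. A locus
#' counts once per cancer type/group it matches, so group counts can sum
#' to more than the number of matched loci.
#'
#' @param cands list of matched `"pai_candidate"` objects.
#' @param groups optional `data.frame` with columns `code`, `group`;
#'   default is the packaged grouping table.
#' @return A list with `n_matched`, `by_scna_type` (named vector),
#'   `by_code` (named vector), `by_group` (named vector or `NULL`).
#' @export
summarize_candidates <- function(cands, groups = NULL) {
  if (is.null(groups)) {
    gp <- system.file("extdata", "tumor_code_groups.tsv",
                      package = "smartddpcr")
    if (nzchar(gp)) groups <- utils::read.delim(gp, stringsAsFactors = FALSE)
  }
  if (any(vapply(cands, function(cc) !isTRUE(cc$matched) && !identical(cc$matched, FALSE),
                 logical(1))))
    abort_validation("candidates must be run through match_cancer_types() first")
  matched <- Filter(function(cc) isTRUE(cc$matched), cands)
  scna <- vapply(matched, function(cc) cc$region$scna_type, character(1))
  codes <- lapply(matched, function(cc) cc$matched_types)
  by_code <- sort(table(unlist(codes)), decreasing = TRUE)
  by_group <- NULL
  if (!is.null(groups)) {
    check_columns(groups, c("code", "group"), file = "groups")
    grp <- lapply(codes, function(cs) {
      g <- groups$group[match(cs, groups$code)]
      unique(ifelse(is.na(g), cs, g))
    })
    by_group <- sort(table(unlist(grp)), decreasing = TRUE)
  }
  list(
    n_matched = length(matched),
    by_scna_type = table(factor(scna, levels = c("amplification", "deletion"))),
    by_code = by_code,
    by_group = by_group
  )
}

#' Candidates from the packaged recurrent-SCNA fixture
#'
#' Builds `"pai_candidate"` objects directly from the packaged table of 16
#' recurrent SCNA peaks, using the printed per-locus association cancer
#' lists as pseudo-SNP trait phrases (the fixture encodes the published
#' per-locus association summary rather than individual catalog rows).
#'
#' @return A list of unmatched `"pai_candidate"` objects (run
#'   [match_cancer_types()] to fill the match fields).
#' @export
table2_candidates <- function() {
  regions <- load_fixture("table2_loci")
  lapply(seq_len(nrow(regions)), function(i) {
    structure(list(
      region = regions[i, , drop = FALSE],
      snps = data.frame(
        rsid = NA_character_, chrom = regions$chrom[i],
        pos = regions$start[i], trait = regions$assoc_cancers[i],
        mapped_genes = "", stringsAsFactors = FALSE
      ),
      matched = NA, matched_types = character(0)
    ), class = "pai_candidate")
  })
}
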