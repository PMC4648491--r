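make_regions <- function() {
  scna_regions(data.frame(
    peak_name = c("CDKN2A", "MYC", "9p21.2"),
    cytoband = c("9p21.3", "8q24.21", "9p21.2"),
    chrom = c("9", "8", "9"),
    start = c(21865498, 128739772, 27572512),
    end = c(22448737, 128762863, 28982153),
    scna_type = c("deletion", "amplification", "deletion"),
    peak_genes = c("CDKN2A", "MYC", ""),
    tumor_types = c("BLCA,BRCA,GBM", "BLCA,BRCA,KIRC,OV", "UCEC"),
    stringsAsFactors = FALSE
  ))
}

make_snps <- function() {
  gwas_snps(data.frame(
    rsid = c("rs_pos_in", "rs_at_end", "rs_gene_only", "rs_outside",
             "rs_other_chrom"),
    chrom = c("9", "9", "8", "9", "7"),
    pos = c(21984661, 22448737, 129500000, 25000000, 21984661),
    trait = c("Glioma", "Breast cancer", "Ovarian cancer", "Glioma",
              "Glioma"),
    mapped_genes = c("CDKN2A", "CDKN2A-AS1", "MYC", "OTHER", "OTHER"),
    stringsAsFactors = FALSE
  ))
}

test_that("SNPs join regions by inclusive position or by peak gene", {
  cands <- overlap_snps(make_regions(), make_snps())
  expect_length(cands, 2)  # 9p21.2 gathers nothing and is omitted
  names(cands) <- vapply(cands, function(cc) cc$region$peak_name,
                         character(1))
  # position inside, position exactly at the end coordinate, gene rule
  expect_setequal(cands$CDKN2A$snps$rsid, c("rs_pos_in", "rs_at_end"))
  expect_equal(cands$MYC$snps$rsid, "rs_gene_only")
})

test_that("overlap is invariant to shuffling and monotone in the gene rule", {
  regions <- make_regions(); snps <- make_snps()
  base <- overlap_snps(regions, snps)
  shuf <- overlap_snps(regions[c(3, 1, 2), ], snps[c(4, 2, 5, 1, 3), ])
  key <- function(cands) {
    k <- lapply(cands, function(cc)
      paste(cc$region$peak_name, paste(sort(cc$snps$rsid), collapse = ",")))
    sort(unlist(k))
  }
  expect_equal(key(base), key(shuf))

  # dropping peak genes can only lose candidates/SNPs
  no_genes <- regions
  no_genes$peak_genes <- ""
  reduced <- overlap_snps(no_genes, snps)
  expect_lte(length(reduced), length(base))
  expect_lte(sum(vapply(reduced, function(cc) nrow(cc$snps), numeric(1))),
             sum(vapply(base, function(cc) nrow(cc$snps), numeric(1))))
})

test_that("genome-build mismatches are rejected", {
  r <- scna_regions(as.data.frame(make_regions()), genome_build = "hg19")
  s <- gwas_snps(as.data.frame(make_snps()), genome_build = "hg38")
  expect_error(overlap_snps(r, s), class = "smartddpcr_validation_error")
})

test_that("cancer-type matching uses the vocabulary, not hard-coded logic", {
  vocab <- load_vocab()
  cands <- overlap_snps(make_regions(), make_snps())
  names(cands) <- vapply(cands, function(cc) cc$region$peak_name,
                         character(1))
  m <- match_cancer_types(cands$CDKN2A, vocab)
  expect_true(m$matched)
  expect_setequal(m$matched_types, c("BRCA", "GBM"))

  # glioma against a bladder/breast-only region: no match
  r2 <- make_regions(); r2$tumor_types <- "BLCA,BRCA"
  c2 <- match_cancer_types(overlap_snps(r2, make_snps()[1, ])[[1]], vocab)
  expect_false(c2$matched)

  # unmapped phrases are reported, not dropped
  s3 <- make_snps()[1, ]; s3$trait <- "Some unknown syndrome"
  expect_warning(
    c3 <- match_cancer_types(overlap_snps(make_regions(), s3)[[1]], vocab),
    "unmapped")
  expect_false(c3$matched)
})

test_that("fixture counts equal a brute-force double loop", {
  vocab <- load_vocab()
  cands <- lapply(table2_candidates(), match_cancer_types, vocab = vocab)
  s <- summarize_candidates(cands)

  # independent oracle: explicit loop over (locus, code) pairs
  regions <- load_fixture("table2_loci")
  oracle_by_code <- new.env()
  oracle_matched <- 0
  for (i in seq_len(nrow(regions))) {
    phrases <- trimws(strsplit(regions$assoc_cancers[i], ";")[[1]])
    codes <- unique(unlist(lapply(tolower(phrases), function(ph) {
      j <- match(ph, vocab$phrase)
      if (is.na(j)) character(0)
      else trimws(strsplit(vocab$codes[j], ",")[[1]])
    })))
    hit <- intersect(strsplit(regions$tumor_types[i], ",")[[1]], codes)
    if (length(hit)) {
      oracle_matched <- oracle_matched + 1
      for (code in hit)
        assign(code, (mget(code, oracle_by_code,
                           ifnotfound = 0)[[1]]) + 1, oracle_by_code)
    }
  }
  expect_equal(s$n_matched, oracle_matched)
  for (code in names(s$by_code))
    expect_equal(unname(s$by_code[code]), get(code, oracle_by_code))
})

test_that("the GWAS catalog reader skips unusable rows and BED converts", {
  cat_path <- system.file("extdata", "demo_gwas_catalog.tsv",
                          package = "smartddpcr")
  expect_message(snps <- read_gwas_catalog(cat_path), "skipped 2")
  expect_false(any(grepl(";", snps$rsid)))
  expect_true(all(snps$pos > 0))

  bed <- tempfile(fileext = ".bed")
  writeLines("chr9\t21865497\t22448737\tCDKN2A\tdeletion\tBLCA,GBM\tCDKN2A",
             bed)
  r <- read_bed_regions(bed)
  expect_equal(r$start, 21865498)  # 0-based half-open -> 1-based inclusive
  expect_equal(r$end, 22448737)
})
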