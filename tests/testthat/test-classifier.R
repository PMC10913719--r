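# hand-built 3-species universe: S1 and S3 congeneric (G1), S2 in G2;
# one block shared within the genus, one block shared across genera
toy_universe <- function(k = 15) {
  cached("toy_universe", function() {
    tax <- toy_taxonomy(3, 2)
    withr::with_seed(99, {
      g1 <- random_dna_str(400)
      g2 <- random_dna_str(400)
      g3 <- random_dna_str(400)
    })
    genus_block <- substr(g1, 101, 180)   # S1+S3 -> genus-level k-mers
    domain_block <- substr(g1, 201, 280)  # S1+S2 -> cross-genus (domain) k-mers
    substr(g3, 101, 180) <- genus_block
    substr(g2, 201, 280) <- domain_block
    ref <- structure(list(species_genomes = c(S1 = g1, S2 = g2, S3 = g3),
                          contaminant_ids = character()),
                     class = "mtx_reference")
    list(tax = tax, ref = ref,
         idx = build_kmer_index(ref, tax, k = 15))
  })
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("index k-mers map to the LCA of their source genomes", {
  u <- toy_universe()
  ids <- u$idx$index$ids
  g1 <- u$ref$species_genomes[["S1"]]
  # brute-force source scan per query k-mer, LCA via the taxonomy oracle
  queries <- list(unique_S1 = substr(g1, 1, 15),
                  genus = substr(g1, 120, 134),
                  cross_genus = substr(g1, 220, 234))
  for (q in names(queries)) {
    km <- queries[[q]]
    sources <- names(u$ref$species_genomes)[vapply(
      u$ref$species_genomes, function(g) {
        grepl(km, g, fixed = TRUE) ||
          grepl(oracle_canonical(km), g, fixed = TRUE)
      }, logical(1))]
    expected <- taxonomy_lca(u$tax, sources)
    got <- ids[kidx_lookup(u$idx$ptr, km)]
    expect_equal(got, expected, label = q)
  }
  # spot-check the three designed cases
  expect_equal(ids[kidx_lookup(u$idx$ptr, substr(g1, 120, 134))], "G1")
  expect_equal(ids[kidx_lookup(u$idx$ptr, substr(g1, 220, 234))], "D1")
})

test_that("error-free reads from unique regions classify with confidence 1", {
  u <- toy_universe()
  read <- substr(u$ref$species_genomes[["S1"]], 1, 60)  # unique region
  res <- classify_reads(make_reads(read), u$idx, confidence = 0.05)
  expect_equal(res$taxon_id, "S1")
  expect_equal(res$confidence, 1)
})

# total k-mer hits per read, via the exported lookup (test helper)
valid_kmer_hits <- function(idx, seqs) {
  vapply(seqs, function(s) {
    kms <- substring(s, seq_len(nchar(s) - idx$k + 1L),
                     seq_len(nchar(s) - idx$k + 1L) + idx$k - 1L)
    sum(kidx_lookup(idx$ptr, kms) > 0)
  }, numeric(1), USE.NAMES = FALSE)
}

test_that("confidence thresholds 0 and 1 have the boundary semantics", {
  u <- toy_universe()
  g1 <- u$ref$species_genomes[["S1"]]
  reads <- make_reads(c(
    substr(g1, 1, 40),                       # all k-mers hit S1
    paste0(substr(g1, 1, 20), strrep("A", 20)),  # partial hits
    strrep("AC", 20)                         # no hits (likely)
  ))
  at0 <- classify_reads(reads, u$idx, 0)
  at1 <- classify_reads(reads, u$idx, 1)
  # threshold 0: any read with >= 1 hit is classified
  hits <- valid_kmer_hits(u$idx, reads$seq)
  expect_equal(!is.na(at0$taxon_id), hits > 0)
  # threshold 1: only reads with 100% in-clade k-mers stay at a species
  expect_equal(at1$taxon_id[1], "S1")
  expect_equal(at1$confidence[1], 1)
  expect_true(is.na(at1$taxon_id[2]) ||
                u$tax$rank[match(at1$taxon_id[2], u$tax$taxon_id)] != "species")
})

test_that("reads spanning a shared block keep their species call while the
           species-clade fraction clears the threshold", {
  u <- toy_universe()
  g1 <- u$ref$species_genomes[["S1"]]
  # half the read in the genus-shared block, half in S1-unique sequence
  read <- substr(g1, 150, 209)  # 30 bases shared tail + 30 unique
  res <- classify_reads(make_reads(read), u$idx, 0.05)
  expect_equal(res$taxon_id, "S1")
  expect_lt(res$confidence, 1)
  # at an extreme threshold the same read ascends off the species
  res_hi <- classify_reads(make_reads(read), u$idx, 0.99)
  expect_true(is.na(res_hi$taxon_id) || res_hi$taxon_id != "S1")
})

test_that("classification agrees with the exhaustive path-score oracle", {
  tax <- toy_taxonomy(5, 3)
  withr::with_seed(7, {
    genomes <- setNames(vapply(1:5, function(i) random_dna_str(300),
                               character(1)), paste0("S", 1:5))
    # congeneric pairs (S1,S4) and (S2,S5) share blocks
    substr(genomes[["S4"]], 50, 109) <- substr(genomes[["S1"]], 50, 109)
    substr(genomes[["S5"]], 120, 179) <- substr(genomes[["S2"]], 120, 179)
    ref <- structure(list(species_genomes = genomes,
                          contaminant_ids = character()),
                     class = "mtx_reference")
    idx <- build_kmer_index(ref, tax, k = 15)
    reads <- perfect_reads(genomes, 50, 40, seed = 8)
  })
  for (thr in c(0, 0.3, 0.6, 1)) {
    got <- classify_reads(reads, idx, thr)
    want <- oracle_classifier(genomes, tax, 15, reads$seq, thr)
    expect_equal(got$taxon_id, want, label = paste("threshold", thr))
  }
})

test_that("classification conserves reads and too-short reads are unclassified", {
  u <- toy_universe()
  reads <- perfect_reads(u$ref$species_genomes, 40, 40, seed = 3)
  res <- classify_reads(reads, u$idx, 0.05)
  expect_equal(sum(!is.na(res$taxon_id)) + sum(is.na(res$taxon_id)),
               nrow(reads))
  short <- classify_reads(make_reads("ACGTACGT"), u$idx, 0)
  expect_true(is.na(short$taxon_id))
  expect_equal(short$confidence, 0)
})

test_that("raising the confidence threshold never classifies more reads", {
  u <- toy_universe()
  reads <- perfect_reads(u$ref$species_genomes, 80, 40, seed = 31)
  prev_classified <- Inf
  for (thr in c(0, 0.05, 0.2, 0.5, 0.9)) {
    res <- classify_reads(reads, u$idx, thr)
    n_cls <- sum(!is.na(res$taxon_id))
    expect_lte(n_cls, prev_classified)
    prev_classified <- n_cls
  }
})

test_that("species reestimation redistributes internal counts proportionally", {
  tax <- toy_taxonomy(2, 1)
  # identity: all counts already at species rank
  prof <- tax_profile(tibble::tibble(taxon_id = c("S1", "S2"),
                                     read_count = c(30, 10)), tax)
  out <- reestimate_species(prof, tax)
  expect_equal(sort(out$read_count), c(10, 30))
  # genus 10 over direct counts 30 and 10 -> +7.5 / +2.5 (one-line oracle)
  prof <- tax_profile(tibble::tibble(taxon_id = c("G1", "S1", "S2"),
                                     read_count = c(10, 30, 10)), tax)
  out <- reestimate_species(prof, tax)
  expect_equal(out$read_count[out$taxon_id == "S1"], 30 + 10 * 30 / 40)
  expect_equal(out$read_count[out$taxon_id == "S2"], 10 + 10 * 10 / 40)
  # fallback: zero direct counts, k-mer totals 2:1 -> 8 / 4
  prof <- tax_profile(tibble::tibble(taxon_id = "G1", read_count = 12), tax)
  kt <- tibble::tibble(taxon_id = c("S1", "S2"), n_kmers = c(200, 100))
  out <- reestimate_species(prof, tax, kt)
  expect_equal(out$read_count[out$taxon_id == "S1"], 8)
  expect_equal(out$read_count[out$taxon_id == "S2"], 4)
})

test_that("reestimation conserves total read count for arbitrary profiles", {
  tax <- toy_taxonomy(6, 3)
  withr::with_seed(13, {
    for (i in 1:10) {
      nodes <- sample(tax$taxon_id[tax$rank %in% c("genus", "species",
                                                   "phylum")], 5)
      prof <- tax_profile(tibble::tibble(taxon_id = nodes,
                                         read_count = rpois(5, 20) + 1), tax)
      out <- suppressWarnings(reestimate_species(prof, tax))
      expect_equal(sum(out$read_count), sum(prof$read_count))
      expect_equal(sum(out$rel_abundance), 1, tolerance = 1e-9)
      expect_true(all(out$rank == "species"))
    }
  })
})
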