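test_that("prescreen applies the abundance threshold with deterministic order", {
  prof <- tax_profile(tibble::tibble(taxon_id = c("A", "B", "C"),
                                     read_count = c(6000, 3995, 5)),
                      rank = "species")
  expect_equal(prescreen(prof, 0.001), c("A", "B"))
  expect_equal(prescreen(prof, 0), c("A", "B", "C"))
  empty <- suppressWarnings(clean_profile(
    tax_profile(tibble::tibble(taxon_id = character(),
                               read_count = numeric()), rank = "species")))
  expect_equal(prescreen(empty, 0.001), character())
})

test_that("reads tiled across a gene keep it; clustered reads fail coverage", {
  fix <- small_fixture()
  pg <- fix$reference$pangenome
  gene <- pg[which(pg$length >= 1000)[1], ]
  # 1x tiling: coverage 100% >= 25% -> all reads assigned
  starts <- seq(1, gene$length - 99, by = 100)
  tiled <- make_reads(substring(gene$seq, starts, starts + 99))
  res <- nucleotide_search(tiled, gene)
  expect_equal(res$counts$reads, length(starts))
  expect_equal(nrow(res$unmapped), 0L)
  # 3 overlapping reads on one corner of a long gene: union of covered
  # positions (oracle below) under 25% -> gene dropped, reads unmapped
  corner <- make_reads(substring(gene$seq, c(1, 21, 41), c(100, 120, 140)))
  covered <- rep(FALSE, gene$length)
  covered[1:140] <- TRUE  # position-set union oracle
  expect_lt(100 * sum(covered) / gene$length, 25)
  res2 <- nucleotide_search(corner, gene)
  expect_equal(nrow(res2$counts), 0L)
  expect_equal(nrow(res2$unmapped), 3L)
})

test_that("reads from non-prescreened species fail the nucleotide tier but can
           be recovered by the translated tier as unclassified", {
  fix <- small_fixture()
  ref <- fix$reference
  pool_s1 <- pangenome_subset(ref, "S1")
  reads_s2 <- perfect_reads(pangenome_subset(ref, "S2")$seq, 20, 99, seed = 5)
  nuc <- nucleotide_search(reads_s2, pool_s1)
  expect_equal(nrow(nuc$counts), 0L)
  expect_equal(nrow(nuc$unmapped), 20L)
  trans <- translated_search(nuc$unmapped, ref$protein_db)
  expect_gt(sum(trans$counts$reads), 0)
  expect_true(all(startsWith(trans$counts$gene_family_id, "UF_S2")))
  # random reads stay unmapped
  rnd <- withr::with_seed(9, make_reads(vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 99, replace = TRUE), collapse = "")
  }, character(1))))
  trans_rnd <- translated_search(rnd, ref$protein_db)
  expect_equal(trans_rnd$unmapped_count, 5L)
  # empty input -> empty result
  empty <- translated_search(nuc$unmapped[0, ], ref$protein_db)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("RPK and CPM follow their definitions and sum to one million", {
  nuc <- list(counts = tibble::tibble(
    gene_id = c("g1", "g2"), gene_family_id = c("f1", "f2"),
    species_id = c("S1", "S2"), length = c(1000L, 2500L),
    reads = c(100L, 250L)))
  fp <- quantify(nuc)
  expect_equal(fp$rpk[fp$gene_family_id == "f1"], 100)
  expect_equal(fp$rpk[fp$gene_family_id == "f2"], 100)
  expect_equal(sum(fp$cpm), 1e6, tolerance = 1e-3)
  # two rows with RPK 300 and 100 -> CPM 750k / 250k
  nuc2 <- list(counts = tibble::tibble(
    gene_id = c("g1", "g2"), gene_family_id = c("f1", "f2"),
    species_id = c("S1", "S1"), length = c(1000L, 1000L),
    reads = c(300L, 100L)))
  fp2 <- quantify(nuc2)
  expect_equal(sort(fp2$cpm), c(250000, 750000))
})

test_that("the tiered pipeline conserves reads and maps everything on clean
           error-free mock data", {
  fix <- small_fixture()
  idx <- small_index()
  rs <- simulate_sample(fix$reference, fix$community, 0, 6000, seed = 30,
                        error_rate = 0, rrna_frac = 0, virus_frac = 0,
                        low_q_tail_frac = 0)
  prof <- profile_kmer(rs, idx, 0)
  species <- prescreen(clean_profile(prof), 0.001)
  expect_setequal(species, fix$community$species_id)
  nuc <- nucleotide_search(rs, pangenome_subset(fix$reference, species))
  trans <- translated_search(nuc$unmapped, fix$reference$protein_db)
  # read conservation: nucleotide + translated + unmapped = input
  expect_equal(sum(nuc$counts$reads) + sum(trans$counts$reads) +
                 trans$unmapped_count, nrow(rs))
  fp <- quantify(nuc, trans, fix$reference)
  expect_equal(attr(fp, "unmapped_count") + sum(fp$reads), nrow(rs))
  expect_equal(sum(fp$cpm), 1e6, tolerance = 1e-3)
  # error-free, all species prescreened: nothing is unmapped
  expect_equal(attr(fp, "unmapped_count"), 0L)
})

test_that("gene-family detection shrinks as host content rises", {
  fix <- small_fixture()
  idx <- small_index()
  n_fams <- vapply(c(0, 0.9, 0.99), function(hf) {
    rs <- simulate_sample(fix$reference, fix$community, hf, 8000, seed = 12)
    pp <- preprocess(rs, fix$reference)
    prof <- clean_profile(profile_kmer(pp$reads, idx, 0.05))
    fp <- run_functional_profiling(pp$reads, prof, fix$reference)
    dplyr::n_distinct(fp$gene_family_id)
  }, numeric(1))
  expect_true(all(diff(n_fams) <= 0))
  expect_lt(n_fams[3], n_fams[1])
})

test_that("a sparser taxonomic input yields no more gene families than a
           sensitive one on a low-biomass sample", {
  fix <- small_fixture()
  idx <- small_index()
  mdb <- cached("small_mdb", function() {
    build_marker_db(small_fixture()$reference, marker_len = 150,
                    markers_per_species = 10, seed = 3)
  })
  rs <- simulate_sample(fix$reference, fix$community, 0.95, 20000, seed = 14)
  pp <- preprocess(rs, fix$reference)
  kp <- clean_profile(profile_kmer(pp$reads, idx, 0.05))
  mp <- clean_profile(profile_markers(pp$reads, mdb))
  fp_k <- run_functional_profiling(pp$reads, kp, fix$reference)
  fp_m <- run_functional_profiling(pp$reads, mp, fix$reference)
  expect_gte(dplyr::n_distinct(fp_k$gene_family_id),
             dplyr::n_distinct(fp_m$gene_family_id))
  tt_k <- attr(fp_k, "tier_totals"); tt_m <- attr(fp_m, "tier_totals")
  expect_gte(tt_k[["nucleotide"]], tt_m[["nucleotide"]])
})
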