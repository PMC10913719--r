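test_that("toy reference mirrors the mock layout and is seed-deterministic", {
  fix <- small_fixture()
  expect_equal(nrow(fix$community), 20L)
  expect_equal(dplyr::n_distinct(fix$community$genus_id), 18L)
  expect_equal(sum(fix$community$cell_fraction), 1, tolerance = 1e-12)
  # pangenome genes are substrings of their genome
  with_gene <- fix$reference$pangenome[c(1, 25, 60), ]
  for (i in seq_len(nrow(with_gene))) {
    expect_true(grepl(with_gene$seq[i],
                      fix$reference$species_genomes[[with_gene$species_id[i]]],
                      fixed = TRUE))
  }
  # every gene maps to exactly one family; peptides stored for each family
  expect_false(anyDuplicated(fix$reference$pangenome$gene_id) > 0)
  expect_setequal(fix$reference$protein_db$gene_family_id,
                  fix$reference$pangenome$gene_family_id)
  # byte-identical regeneration under the same seed
  fix2 <- build_toy_reference(n_species = 20, n_genera = 18, genome_len = 8000,
                              genes_per_species = 6, seed = 42)
  expect_identical(fix$reference$species_genomes,
                   fix2$reference$species_genomes)
  expect_identical(fix$reference$host, fix2$reference$host)
  path1 <- withr::local_tempfile(); path2 <- withr::local_tempfile()
  write_fasta(fix$reference$species_genomes, path1)
  write_fasta(fix2$reference$species_genomes, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("congeneric species share an identical transcribed block", {
  fix <- small_fixture()
  pair <- fix$community$species_id[fix$community$genus_id == "G1"]
  expect_length(pair, 2L)
  g1 <- fix$reference$species_genomes[[pair[1]]]
  g2 <- fix$reference$species_genomes[[pair[2]]]
  # some 62-mer of the first gene of one genome occurs in the other genome
  first_gene <- fix$reference$pangenome$seq[
    fix$reference$pangenome$species_id == pair[1]][1]
  starts <- seq_len(nchar(first_gene) - 62 + 1)
  shared <- vapply(starts, function(i) {
    grepl(substr(first_gene, i, i + 61), g2, fixed = TRUE)
  }, logical(1))
  expect_true(any(shared))
})

test_that("single-species reference is the degenerate identity case", {
  fix <- build_toy_reference(n_species = 1, n_genera = 1, genome_len = 2000,
                             genes_per_species = 2,
                             gene_len_range = c(300, 600), seed = 3)
  expect_equal(taxonomy_lca(fix$taxonomy, "S1", "S1"), "S1")
  expect_error(build_toy_reference(n_species = 2, n_genera = 3), "n_genera")
  expect_error(build_toy_reference(genome_len = 500, read_len = 100), "10x")
})

test_that("cell-ratio simulation matches the transcript-weight expectation", {
  fix <- small_fixture()
  depth <- 1e5; hf <- 0.97; h <- 20
  rs <- simulate_sample(fix$reference, fix$community, hf, depth, seed = 11,
                        host_weight = h)
  # expected host share among all reads, nuisance fractions off the top
  w_host <- hf * h
  w_mic <- (1 - hf) * sum(fix$community$cell_fraction * fix$community$activity)
  p_host <- (1 - 0.02 - 0.005) * w_host / (w_host + w_mic)
  n_host <- sum(rs$truth == "host")
  expect_lt(abs(n_host - depth * p_host),
            3 * sqrt(depth * p_host * (1 - p_host)))
  expect_equal(nrow(rs), depth)
})

test_that("host-free samples carry no host reads; silent species stay silent", {
  fix <- small_fixture()
  rs <- simulate_sample(fix$reference, fix$community, 0, 5000, seed = 5)
  expect_equal(sum(rs$truth == "host"), 0L)
  comm <- set_activity(fix$community, "S3", 0)
  for (seed in c(1, 2, 3)) {
    rs <- simulate_sample(fix$reference, comm, 0.5, 5000, seed = seed)
    expect_equal(sum(rs$truth == "species:S3"), 0L)
  }
  all_off <- set_activity(fix$community, fix$community$species_id, 0)
  expect_error(simulate_sample(fix$reference, all_off, 0, 1000, seed = 1),
               "empty library")
})

test_that("read-fraction mixing hits exact counts, seeds and errors", {
  fix <- small_fixture()
  mic <- simulate_sample(fix$reference, fix$community, 0, 2000, seed = 1,
                         rrna_frac = 0, virus_frac = 0, id_prefix = "m")
  host <- simulate_sample(fix$reference, fix$community, 1, 2000, seed = 2,
                          rrna_frac = 0, virus_frac = 0, id_prefix = "h")
  mx <- mix_reads(mic, host, host_fraction = 0.9, depth = 1000, seed = 262)
  expect_equal(nrow(mx), 1000L)
  expect_equal(sum(mx$truth == "host"), 900L)
  expect_equal(sum(startsWith(mx$truth, "species:")), 100L)
  # SD100 analog: only host reads
  mx100 <- mix_reads(mic, host, 1, 1500, seed = 262)
  expect_equal(sum(mx100$truth != "host"), 0L)
  # seeded determinism: same seed -> same id multiset; other seed differs
  mx_a <- mix_reads(mic, host, 0.9, 1000, seed = 262)
  mx_b <- mix_reads(mic, host, 0.9, 1000, seed = 988)
  expect_setequal(mx$read_id, mx_a$read_id)
  expect_false(setequal(mx$read_id, mx_b$read_id))
  expect_equal(nrow(mx_b), 1000L)
  # pool exhaustion names the deficient pool
  expect_error(mix_reads(mic, host, 0.99, 3000, seed = 1), "host pool")
  expect_error(mix_reads(mic, host, 0.01, 3000, seed = 1), "microbial pool")
})

test_that("contaminant injection follows the constant-mass 1/concentration model", {
  fix <- cached("contam_fix", function() {
    build_toy_reference(n_species = 8, n_genera = 8, genome_len = 5000,
                        genes_per_species = 4, seed = 9, n_contaminants = 2)
  })
  samples <- lapply(1:8, function(i) {
    simulate_sample(fix$reference, fix$community, 0, 1500, seed = 100 + i)
  })
  names(samples) <- paste0("s", 1:8)
  conc <- setNames(exp(seq(log(0.25), log(4), length.out = 8)), names(samples))
  out <- inject_contaminants(samples, fix$reference, conc, load = 80, seed = 7)
  fr <- truth_frequencies(out)
  ctm <- fr[fr$taxon_id == "C1", ]
  # frequency decays with concentration (negative Spearman correlation)
  rho <- cor(ctm$frequency, conc[ctm$sample_id], method = "spearman")
  expect_lt(rho, 0)
  # zero contaminant taxa -> identity
  same <- inject_contaminants(samples, fix$reference, conc,
                              contaminant_ids = character())
  expect_identical(same, samples)
})

test_that("truth labels partition every read set", {
  fix <- small_fixture()
  rs <- simulate_sample(fix$reference, fix$community, 0.7, 4000, seed = 8)
  kinds <- sub(":.*", "", rs$truth)
  expect_true(all(kinds %in% c("host", "rrna", "virus", "species")))
  expect_equal(nrow(rs), 4000L)
})
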