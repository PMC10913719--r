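# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small 20-species/18-genus universe for fast unit tests
small_fixture <- function() {
  cached("small", function() {
    build_toy_reference(n_species = 20, n_genera = 18, genome_len = 8000,
                        genes_per_species = 6, seed = 42)
  })
}

small_index <- function() {
  cached("small_idx", function() build_kmer_index(small_fixture()$reference))
}

# full-size universe used by the acceptance-level checks
full_fixture <- function() {
  cached("full", function() build_toy_reference(seed = 1))
}

full_index <- function() {
  cached("full_idx", function() build_kmer_index(full_fixture()$reference))
}

# tiny 5-node taxonomy (root, domain, phylum, 1 genus, 2 species + 1 extra
# genus/species) for hand-enumerable LCA/classification cases
tiny_taxonomy <- function() toy_taxonomy(n_species = 3, n_genera = 2)

# brute-force canonical k-mer of a string window (oracle helper)
oracle_canonical <- function(kmer) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  min(kmer, rc)
}

oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  vapply(seq_len(n - k + 1L), function(i) {
    oracle_canonical(substr(seq, i, i + k - 1L))
  }, character(1))
}

# independent read classifier: brute-force k-mer lookup over genome scans,
# path-score maximization and confidence ascent in plain R
oracle_classifier <- function(genomes, taxonomy, k, reads, threshold) {
  kmer_taxon <- list()
  for (sp in names(genomes)) {
    for (km in unique(oracle_kmers(genomes[[sp]], k))) {
      kmer_taxon[[km]] <- unique(c(kmer_taxon[[km]], sp))
    }
  }
  kmer_lca <- vapply(kmer_taxon, function(sps) {
    taxonomy_lca(taxonomy, sps)
  }, character(1))
  idx_of <- function(id) match(id, taxonomy$taxon_id)
  vapply(reads, function(rd) {
    kms <- oracle_kmers(rd, k)
    valid <- length(kms)
    hits <- kmer_lca[match(kms, names(kmer_lca))]
    hits <- hits[!is.na(hits)]
    if (valid == 0 || length(hits) == 0) return(NA_character_)
    hit_tab <- table(hits)
    clade <- function(node) {
      in_clade <- vapply(names(hit_tab), function(h) {
        node %in% taxonomy_ancestors(taxonomy, h)
      }, logical(1))
      sum(hit_tab[in_clade])
    }
    path_score <- function(node) {
      anc <- taxonomy_ancestors(taxonomy, node)
      sum(hit_tab[names(hit_tab) %in% anc])
    }
    cand <- names(hit_tab)
    scores <- vapply(cand, path_score, numeric(1))
    depths <- c(root = 0, domain = 1, phylum = 2, genus = 3, species = 4)[
      taxonomy$rank[idx_of(cand)]]
    ord <- order(-scores, -depths, idx_of(cand))
    node <- cand[ord[1]]
    while (!is.na(node)) {
      if (clade(node) / valid >= threshold) return(node)
      node <- taxonomy$parent_id[idx_of(node)]
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# error-free reads tiled or sampled from a sequence
perfect_reads <- function(seqs, n, read_len, seed = 1) {
  withr::with_seed(seed, {
    pool <- unname(unlist(seqs))
    src <- sample(seq_along(pool), n, replace = TRUE)
    start <- vapply(src, function(i) {
      sample.int(nchar(pool[i]) - read_len + 1L, 1)
    }, integer(1))
    tibble::tibble(
      read_id = paste0("pr", seq_len(n)),
      seq = substring(pool[src], start, start + read_len - 1L),
      qual = strrep("I", read_len),
      truth = "test"
    )
  })
}

make_reads <- function(seqs, quals = strrep("I", nchar(seqs))) {
  tibble::tibble(read_id = paste0("q", seq_along(seqs)), seq = seqs,
                 qual = quals, truth = "test")
}
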