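# a tiny hand-made genome table for exact-value checks
toy_genome <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    strand = "+",
    cds = c("ATGAAATAA",                    # protein MK
            "ATGGCCGCCGCCGCCTGA",           # M + 4x GCC Ala
            "GTGGAAGAACAGTAA"),             # (V)EEQ
    upstream50 = c(strrep("GC", 25), strrep("AT", 25), strrep("GCAT", 12)),
    protein = translatomics:::translate_cds(c("ATGAAATAA", "ATGGCCGCCGCCGCCTGA",
                                              "GTGGAAGAACAGTAA")),
    is_pseudogene = c(FALSE, FALSE, FALSE),
    length_ok = TRUE
  )
}

test_that("random gene sets are reproducible, pseudogene-free and well sized", {
  cfg <- small_cfg()
  sg <- simulate_genome(cfg, seed = 3)
  s1 <- sample_random_sets(sg$genome, 20, n_sets = 50, seed = 9)
  s2 <- sample_random_sets(sg$genome, 20, n_sets = 50, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(lengths(s1) == 20))
  pseudo <- sg$genome$gene_id[sg$genome$is_pseudogene]
  expect_false(any(unlist(s1) %in% pseudo))
  expect_error(sample_random_sets(sg$genome, 10000, 10, 1), "exceeds")

  # set_size = eligible count -> every set is the full eligible list
  eligible <- sg$genome$gene_id[!sg$genome$is_pseudogene]
  full <- sample_random_sets(sg$genome, length(eligible), n_sets = 3, seed = 2)
  expect_true(all(vapply(full, function(s) setequal(s, eligible), logical(1))))

  # inclusion frequency approximately uniform
  sets <- sample_random_sets(sg$genome, 20, n_sets = 1000, seed = 5)
  freq <- table(factor(unlist(sets), levels = eligible)) / 1000
  p <- 20 / length(eligible)
  expect_true(all(abs(freq - p) < 5 * sqrt(p * (1 - p) / 1000)))
})

test_that("amino-acid frequencies are pooled per-100 and sum to 100", {
  g <- toy_genome()
  af <- aa_frequency(g, "gA")          # protein "MK"
  expect_equal(af$freq[af$aa == "M"], 50)
  expect_equal(af$freq[af$aa == "K"], 50)
  expect_equal(sum(af$freq), 100)
  expect_equal(sum(aa_frequency(g)$freq), 100)
})

test_that("G+C windows compute exact percentages", {
  expect_equal(gc_windows(tibble::tibble(
    gene_id = "x", strand = "+", cds = "GGCC", upstream50 = "ATAT",
    protein = "", is_pseudogene = FALSE, length_ok = FALSE))$full_cds_gc, 100)
  g <- gc_windows(toy_genome())
  expect_equal(g$upstream50_gc, c(100, 0, 50))
  expect_equal(g$downstream50_gc[1], 100 * 1 / 9)  # GC of ATGAAATAA
  expect_true(all(g$full_cds_gc >= 0 & g$full_cds_gc <= 100))
  expect_equal(g$upstream_complete, c(TRUE, TRUE, FALSE))
})

test_that("the positional G+C profile matches hand-windowed values", {
  g <- tibble::tibble(
    gene_id = "x", strand = "+",
    cds = strrep("G", 60), upstream50 = strrep("A", 50),
    protein = "", is_pseudogene = FALSE, length_ok = TRUE
  )
  pr <- gc_positional_profile(g, half_window = 2, positions = c(-10, -1, 1, 10))
  # window at -10 covers labels -12..-8: all A -> 0
  expect_equal(pr$gc[pr$position == -10], 0)
  # a window crossing the (nonexistent) position 0 holds 2*hw labels:
  # at -1 it covers -3..-1 and +1 (one G of four bases)
  expect_equal(pr$gc[pr$position == -1], 100 * 1 / 4)
  # at +1 it covers -1 and +1..+3 (three G of four bases)
  expect_equal(pr$gc[pr$position == 1], 100 * 3 / 4)
  expect_equal(pr$gc[pr$position == 10], 100)

  # all-G sequences profile at 100% everywhere covered
  g2 <- dplyr::mutate(g, upstream50 = strrep("G", 50))
  pr2 <- gc_positional_profile(g2, half_window = 12)
  expect_true(all(pr2$gc[pr2$n_genes > 0] == 100))

  # positions beyond the sequence are excluded, not zero-filled
  pr3 <- gc_positional_profile(g, half_window = 2, positions = c(60, 61, 100))
  expect_equal(pr3$n_genes, c(1L, 0L, 0L))
})

test_that("RSCU matches its definition and identities", {
  g <- toy_genome()
  # gene gB uses only GCC among alanine's four codons -> RSCU(GCC) = 4
  r <- rscu(g, "gB")
  ala <- r[r$aa == "A", ]
  expect_equal(ala$rscu[ala$codon == "GCC"], 4)
  expect_equal(sum(ala$rscu[ala$codon != "GCC"]), 0)

  expect_equal(nrow(r), 59)
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% r$codon))

  # family means are exactly 1 wherever the family is used
  cfg <- small_cfg()
  sg <- simulate_genome(cfg, seed = 6)
  rr <- rscu(sg$genome)
  fm <- rr |> dplyr::group_by(aa) |> dplyr::summarise(m = mean(rscu))
  expect_true(all(abs(fm$m - 1) < 1e-12))

  # uniform synonymous usage -> RSCU = 1 everywhere in the family
  gu <- tibble::tibble(
    gene_id = "u", strand = "+",
    cds = paste0("ATG", "GCA", "GCC", "GCG", "GCT", "TAA"),
    upstream50 = "", protein = "MAAAA", is_pseudogene = FALSE, length_ok = TRUE
  )
  ru <- rscu(gu, "u")
  expect_equal(ru$rscu[ru$aa == "A"], rep(1, 4))
})

test_that("RSCU and G+C agree with seqinr on pooled coding sequence", {
  skip_if_not_installed("seqinr")
  cfg <- small_cfg()
  sg <- simulate_genome(cfg, seed = 10)
  set <- sg$genome$gene_id[1:25]
  mine <- rscu(sg$genome, set)
  # pool the same interior codons and hand them to seqinr
  interior <- substr(sg$genome$cds[match(set, sg$genome$gene_id)], 4,
                     nchar(sg$genome$cds[match(set, sg$genome$gene_id)]) - 3)
  pooled <- paste(interior, collapse = "")
  ref <- seqinr::uco(seqinr::s2c(pooled), index = "rscu")
  names(ref) <- toupper(names(ref))
  # seqinr normalizes over all synonymous codons incl. families of size 1
  cmp <- mine[!is.na(mine$rscu), ]
  expect_equal(cmp$rscu, unname(ref[cmp$codon]), tolerance = 1e-10)

  gc_ref <- 100 * seqinr::GC(seqinr::s2c(sg$genome$cds[1]))
  expect_equal(gc_windows(sg$genome)$full_cds_gc[1], gc_ref, tolerance = 1e-10)
})

test_that("start and stop codon usage percentages are exact", {
  g <- toy_genome()
  u <- start_stop_usage(g)
  expect_equal(u$percent[u$category == "start" & u$codon == "ATG"], 100 * 2 / 3)
  expect_equal(u$percent[u$category == "start" & u$codon == "GTG"], 100 * 1 / 3)
  expect_equal(u$percent[u$category == "stop" & u$codon == "TAA"], 100 * 2 / 3)
  expect_equal(u$percent[u$category == "stop" & u$codon == "TGA"], 100 * 1 / 3)
  for (cat in c("start", "stop")) {
    expect_equal(sum(u$percent[u$category == cat]), 100)
  }
})

test_that("length statistics flag a short set and calibrate on random sets", {
  cfg <- small_cfg()
  sg <- simulate_genome(cfg, seed = 12)
  te_set <- sg$truth$gene_id[sg$truth$in_te_set]
  nulls <- sample_random_sets(sg$genome, length(te_set), n_sets = 300, seed = 13)
  ls <- protein_length_stats(te_set, sg$genome, nulls)
  expect_lt(ls$z, -2)
  expect_equal(ls$significant, TRUE)
  expect_equal(ls$direction, "lower")
  expect_lt(ls$wilcox_p, 0.01)
  expect_error(protein_length_stats(character(0), sg$genome, nulls), "empty")

  # a single gene of median length is unremarkable under the Wilcoxon test
  len <- nchar(sg$genome$protein)
  med_gene <- sg$genome$gene_id[which.min(abs(len - median(len)))]
  ls1 <- protein_length_stats(med_gene, sg$genome, nulls)
  expect_gt(ls1$wilcox_p, 0.2)
})

test_that("a random gene set rarely triggers battery flags", {
  cfg <- small_cfg()
  sg <- simulate_genome(cfg, seed = 15)
  set.seed(16)
  eligible <- sg$genome$gene_id[!sg$genome$is_pseudogene]
  rates <- vapply(1:5, function(i) {
    rs <- sample(eligible, 30)
    glance(composition_battery(rs, sg$genome, n_sets = 300, seed = 400 + i))$flag_rate
  }, numeric(1))
  expect_lte(mean(rates), 0.15)
})
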