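test_that("reading a regulatory set preserves counts and round-trips", {
  toy <- write_toy_dataset()
  rs <- read_regulatory_set(toy$fasta, toy$bed, toy$motifs)
  expect_equal(nrow(rs$modules), 2)
  expect_equal(nrow(rs$annotations), 3)
  expect_length(rs$motifs, 2)

  # round trip: write what was read, read it again, values identical
  fa2 <- tempfile(fileext = ".fa"); bed2 <- tempfile(fileext = ".bed")
  mot2 <- tempfile(fileext = ".txt")
  write_modules(rs$modules, fa2)
  write_sites(rs$annotations, bed2)
  write_motifs(rs$motifs, mot2)
  rs2 <- read_regulatory_set(fa2, bed2, mot2)
  expect_equal(rs2$modules, rs$modules)
  expect_equal(rs2$annotations, rs$annotations)
  expect_equal(lapply(rs2$motifs, `[[`, "freq"),
               lapply(rs$motifs, `[[`, "freq"))
})

test_that("malformed inputs are rejected with informative errors", {
  toy <- write_toy_dataset()
  # site extending beyond its module
  bad <- toy$annotations
  bad$end[1] <- 1300L
  bedbad <- tempfile(fileext = ".bed")
  write_sites(bad, bedbad)
  expect_error(read_regulatory_set(toy$fasta, bedbad, toy$motifs),
               "outside their module")
  # unknown factor
  bad2 <- toy$annotations
  bad2$factor[2] <- "nosuch"
  write_sites(bad2, bedbad)
  expect_error(read_regulatory_set(toy$fasta, bedbad, toy$motifs),
               "no motif for factor")
  # malformed matrix
  mm <- tempfile(fileext = ".txt")
  writeLines(c(">broken", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), mm)
  expect_error(read_motifs(mm), "malformed|expected 4 rows")
})

test_that("minus-strand sites are reverse-complemented into motif frame", {
  toy <- write_toy_dataset()
  rs <- read_regulatory_set(toy$fasta, toy$bed, toy$motifs)
  inst <- extract_site_sequences(rs$modules, rs$annotations, rs$motifs)
  ann <- rs$annotations[2, ]  # the minus-strand site, length == L
  mod <- rs$modules[rs$modules$id == ann$module_id, ]
  slice <- substr(mod$sequence, ann$start - mod$start + 1,
                  ann$end - mod$start)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice)))
  expect_equal(inst$sequence[2], rc)
  # plus-strand identity case: exact slice
  ann1 <- rs$annotations[1, ]
  expect_equal(inst$sequence[1],
               substr(mod$sequence, ann1$start - mod$start + 1,
                      ann1$end - mod$start))
  expect_true(all(nchar(inst$sequence) == 7))
})

test_that("length-mismatched footprints take the max-fitness window", {
  bg <- uniform_bg()
  m <- random_motif(7, "tf", seed = 42, concentration = 0.1)
  land <- build_fitness(m, bg)
  set.seed(9)
  sq <- sample_markov(bg, 60, 1)
  modules <- data.frame(id = "m", chrom = "m", start = 0L, end = 60L,
                        sequence = sq, stringsAsFactors = FALSE)
  # annotation of length L + 2: brute-force over all overlapping windows
  ann <- data.frame(module_id = "m", chrom = "m", start = 20L, end = 29L,
                    strand = "+", factor = "tf", stringsAsFactors = FALSE)
  inst <- extract_site_sequences(modules, ann, list(tf = m))
  cand <- seq(max(0, 20 - 6), 28)
  fits <- vapply(cand, function(w)
    site_fitness(land, substr(sq, w + 1, w + 7)), numeric(1))
  expect_equal(inst$window_start, cand[which.max(fits)])
  expect_equal(inst$sequence,
               substr(sq, inst$window_start + 1, inst$window_start + 7))
  expect_equal(site_fitness(land, inst$sequence), max(fits))

  # module of exactly L bp with a shorter annotation: single candidate
  modules2 <- data.frame(id = "m2", chrom = "m2", start = 0L, end = 7L,
                         sequence = substr(sq, 1, 7),
                         stringsAsFactors = FALSE)
  ann2 <- data.frame(module_id = "m2", chrom = "m2", start = 0L, end = 6L,
                     strand = "+", factor = "tf", stringsAsFactors = FALSE)
  inst2 <- extract_site_sequences(modules2, ann2, list(tf = m))
  expect_equal(inst2$sequence, substr(sq, 1, 7))
})

test_that("curation filters are enforced and idempotent", {
  ann <- data.frame(
    module_id = c("m1", "m2", "m1", "m1", "m1", "m3", "m4", "mX"),
    chrom = c("chr2", "chr2", "chr2", "chr2", "chr2", "chr3", "chr3",
              "chrX"),
    start = c(0L, 100L, 10L, 14L, 40L, 0L, 50L, 0L),
    end = c(7L, 107L, 17L, 21L, 47L, 7L, 57L, 7L),
    strand = "+",
    factor = c("fA", "fA", "fB", "fB", "singleton", "fC", "fC", "fA"),
    stringsAsFactors = FALSE)
  cur <- curate_sites(ann)
  # singleton factor removed (one module only)
  expect_false("singleton" %in% cur$factor)
  # the two mutually overlapping fB sites both removed
  expect_false("fB" %in% cur$factor)
  # X-chromosome site removed
  expect_false(any(cur$chrom == "chrX"))
  # fC survives (two modules, no overlaps);
  # fA survives on autosomes only if still in >= 2 modules after X removal
  expect_true(all(c("fA", "fC") %in% cur$factor))
  # idempotent and order-preserving
  expect_identical(curate_sites(cur), cur)
  expect_false(is.unsorted(match(
    paste(cur$module_id, cur$start),
    paste(ann$module_id, ann$start))))
})

test_that("local background estimation behaves at edges and in the bulk", {
  mod <- data.frame(id = "m", chrom = "m", start = 0L, end = 30L,
                    sequence = paste0(strrep("A", 12), "CGCGCG",
                                      strrep("A", 12)),
                    stringsAsFactors = FALSE)
  site <- data.frame(module_id = "m", chrom = "m", start = 12L, end = 18L,
                     strand = "+", factor = "f", stringsAsFactors = FALSE)
  bg <- local_background(mod, site, flank_bp = 12)
  # all-A flanks: concentrated on A yet strictly positive
  expect_gt(bg$p0["A"], 0.9)
  expect_true(all(bg$p0 > 0))
  expect_equal(sum(bg$p0), 1, tolerance = 1e-9)
  expect_equal(bg$q0, sum(bg$p0^2))

  # site at module start: left flank empty, right flank used
  site0 <- transform(site, start = 0L, end = 6L)
  bg0 <- local_background(mod, site0, flank_bp = 6)
  expect_gt(bg0$p0["A"], 0.5)  # right flank is AAAAAA region boundary

  # seeded uniform flanks of 4000 bp: each entry within 3 binomial SEs
  set.seed(4)
  big <- paste0(sample_markov(uniform_bg(), 4000, 1), strrep("N", 0),
                sample_markov(uniform_bg(), 4007, 1))
  modb <- data.frame(id = "b", chrom = "b", start = 0L, end = 8007L,
                     sequence = big, stringsAsFactors = FALSE)
  siteb <- data.frame(module_id = "b", chrom = "b", start = 4000L,
                      end = 4007L, strand = "+", factor = "f",
                      stringsAsFactors = FALSE)
  bgb <- local_background(modb, siteb, flank_bp = 4000)
  se <- sqrt(0.25 * 0.75 / 8000)
  expect_true(all(abs(bgb$p0 - 0.25) < 3 * se))

  # degenerate flanks trigger the module-wide fallback with a warning
  tiny <- data.frame(id = "t", chrom = "t", start = 0L, end = 6L,
                     sequence = "ACGTAC", stringsAsFactors = FALSE)
  sitet <- data.frame(module_id = "t", chrom = "t", start = 0L, end = 6L,
                      strand = "+", factor = "f", stringsAsFactors = FALSE)
  expect_warning(local_background(tiny, sitet, flank_bp = 5),
                 "module-wide")
})
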