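test_that("MGF files round-trip and apply the strict intensity floor", {
  s1 <- spec_of("one", 515.33, c(120.1, 250.2, 400.5),
                c(1000, 5e4, 999.99))
  s2 <- spec_of("two", 600.40, c(130.123456, 270.2), c(2e4, 3e4))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(s1, s2), path)

  spectra <- read_mgf(path, intensity_floor = 1000)
  expect_length(spectra, 2)
  # peak below the floor removed (floor is >=, 999.99 < 1000)
  expect_length(spectra[[1]]$mz, 2)
  # round trip preserves peak positions to 6 decimals
  expect_equal(spectra[[2]]$mz, s2$mz, tolerance = 1e-6)
  expect_equal(spectra[[2]]$intensity, s2$intensity, tolerance = 1e-6)
  expect_identical(spectra[[2]]$spectrum_id, "two")

  # all peaks below floor: spectrum dropped with a warning
  s3 <- spec_of("faint", 300, 150.1, 10)
  path3 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(s3), path3)
  expect_warning(out <- read_mgf(path3), "dropped")
  expect_length(out, 0)

  # malformed peak line reports the line number
  writeLines(c("BEGIN IONS", "PEPMASS=100", "abc def", "END IONS"), path3)
  expect_error(read_mgf(path3), "malformed peak line 3")
})

test_that("greedy fragment matching is one-to-one and complete on identity", {
  a <- spec_of("a", 500, c(100, 200, 300), c(1, 2, 3) * 1e4)
  expect_equal(match_fragments(a, a)$n_matched, 3)
  b <- spec_of("b", 500, c(150, 250), c(1, 1) * 1e4)
  expect_equal(match_fragments(a, b)$n_matched, 0)

  # 10-peak spectra constructed with exactly 6 common fragments
  common <- seq(100, 600, by = 100)
  s1 <- spec_of("s1", 700, c(common, 111, 222, 333, 444))
  s2 <- spec_of("s2", 700, c(common, 151, 261, 371, 481))
  expect_equal(match_fragments(s1, s2, tol_da = 0.05)$n_matched, 6)
})

test_that("greedy pairing matches the exhaustive optimum on small spectra", {
  set.seed(31)
  for (i in 1:40) {
    mza <- sort(runif(6, 100, 400))
    mzb <- sort(mza + rnorm(6, 0, 0.08))  # some in, some out of tolerance
    a <- spec_of("a", 500, mza, runif(6, 1e3, 1e5))
    b <- spec_of("b", 500, mzb, runif(6, 1e3, 1e5))
    expect_equal(match_fragments(a, b, 0.05)$n_matched,
                 max_matching_oracle(mza, mzb, 0.05))
  }
})

test_that("spectral cosine matches hand computation and is symmetric", {
  a <- spec_of("a", 500, c(100, 200, 300))
  expect_equal(spectral_cosine(a, a)$cosine, 1)

  b <- spec_of("b", 510, c(150, 250))
  expect_equal(spectral_cosine(a, b)$cosine, 0)

  # equal intensities, 2 of 3 peaks shared: 2/3
  c1 <- spec_of("c1", 500, c(100, 200, 300))
  c2 <- spec_of("c2", 505, c(100, 200, 411))
  sc <- spectral_cosine(c1, c2)
  expect_equal(sc$cosine, 2 / 3)
  expect_equal(sc$n_matched, 2)

  # symmetry over random spectra
  set.seed(5)
  for (i in 1:10) {
    x <- spec_of("x", 500, sort(runif(8, 100, 450)), runif(8, 1e3, 1e6))
    y <- spec_of("y", 520, sort(runif(8, 100, 450)), runif(8, 1e3, 1e6))
    expect_lt(abs(spectral_cosine(x, y)$cosine -
                  spectral_cosine(y, x)$cosine), 1e-12)
  }
})

test_that("network edges require BOTH the cosine cut and the fragment minimum", {
  # 5 shared peaks out of 5: cosine 1 but only 5 matched -> no edge at min 6
  p5 <- seq(100, 500, by = 100)
  a <- spec_of("a", 600, p5)
  b <- spec_of("b", 600, p5)
  net5 <- build_network(list(a, b), cosine_cut = 0.7, min_matched = 6)
  expect_equal(nrow(net5$edges), 0)
  expect_true(all(net5$nodes$isolated))

  # 6 shared of 8: cosine 0.75 > 0.7 and 6 matched -> edge
  p6 <- seq(100, 600, by = 100)
  c1 <- spec_of("c1", 700, c(p6, 711, 722))
  c2 <- spec_of("c2", 700, c(p6, 751, 762))
  net6 <- build_network(list(c1, c2), cosine_cut = 0.7, min_matched = 6)
  expect_equal(nrow(net6$edges), 1)
  expect_equal(net6$edges$matched, 6)
})

test_that("a planted compound family forms one component; unrelated spectra stay isolated", {
  fam <- gen_compound_family("fam", n_derivatives = 7, scaffold_peaks = 10,
                             seed = 3)
  singles <- lapply(1:5, function(i)
    gen_compound_family(paste0("u", i), n_derivatives = 1,
                        scaffold_peaks = 8,
                        base_precursor_mz = 320 + 55 * i,
                        seed = 100 + i)$spectra[[1]])
  spectra <- c(fam$spectra, singles)
  net <- build_network(spectra, cosine_cut = 0.7, min_matched = 6)
  comp <- network_components(net)
  fam_comp <- unique(comp[names(fam$spectra)])
  expect_length(fam_comp, 1)
  sizes <- table(comp)
  expect_equal(sum(sizes >= 3), 1)           # exactly one family
  expect_equal(unname(sizes[as.character(fam_comp)]), 7L)
  expect_true(all(net$nodes$isolated[net$nodes$id %in%
                                       vapply(singles, `[[`, "", "spectrum_id")]))
})

test_that("edge count is monotone in the cosine cut and the fragment minimum", {
  fam1 <- gen_compound_family("m1", 4, scaffold_peaks = 9, seed = 21)
  fam2 <- gen_compound_family("m2", 4, scaffold_peaks = 9,
                              base_precursor_mz = 430, seed = 22)
  spectra <- c(fam1$spectra, fam2$spectra)
  e_by_cut <- vapply(c(0, 0.3, 0.5, 0.7, 0.9),
                     function(ct) nrow(build_network(spectra, ct, 1)$edges),
                     numeric(1))
  expect_true(all(diff(e_by_cut) <= 0))
  e_by_min <- vapply(c(1, 3, 6, 9, 12),
                     function(mm) nrow(build_network(spectra, 0.1, mm)$edges),
                     numeric(1))
  expect_true(all(diff(e_by_min) <= 0))
})

test_that("library annotation picks the best passing match and ties report both", {
  fam <- gen_compound_family("q", 2, scaffold_peaks = 8, seed = 9)
  spectra <- fam$spectra
  net <- build_network(spectra, 0.7, 6)

  # identical library spectrum annotates its node
  lib1 <- spectra[[1]]; lib1$spectrum_id <- "compound X"
  ann <- annotate_network(net, list(lib1), spectra)
  expect_identical(ann$nodes$annotation[1], "compound X")

  # empty library: unchanged
  expect_identical(annotate_network(net, list(), spectra)$nodes$annotation,
                   net$nodes$annotation)

  # exact tie: both names reported
  lib2 <- spectra[[1]]; lib2$spectrum_id <- "compound Y"
  ann2 <- annotate_network(net, list(lib1, lib2), spectra)
  expect_identical(ann2$nodes$annotation[1], "compound X | compound Y")
})

test_that("graph export round-trips through GraphML and writes edge lists", {
  fam <- gen_compound_family("x", 7, scaffold_peaks = 10, seed = 4)
  net <- build_network(fam$spectra, 0.7, 6)
  expect_gte(nrow(net$edges), 6)

  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, path, "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 7)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true(all(c("precursor_mz", "annotation") %in%
                    igraph::vertex_attr_names(g)))
  expect_true(all(c("cosine", "matched") %in% igraph::edge_attr_names(g)))

  # empty network still exports a valid file
  lone <- build_network(fam$spectra[1], 0.7, 6)
  path2 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(lone, path2, "graphml")
  g2 <- igraph::read_graph(path2, format = "graphml")
  expect_equal(igraph::vcount(g2), 1)
  expect_equal(igraph::ecount(g2), 0)

  path3 <- withr::local_tempfile(fileext = ".tsv")
  export_graph(net, path3, "edgelist")
  el <- read.delim(path3)
  expect_equal(nrow(el), nrow(net$edges))
})
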