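test_that("segment_params validates and stores its fields", {
  sp <- segment_params(418, 2.89, 206.74)
  expect_s3_class(sp, "segment_params")
  expect_equal(sp$m_seg, 418)
  expect_error(segment_params(-1, 2.89, 206.74), "positive")
  expect_error(segment_params(418, 0, 206.74), "positive")
})

test_that("Berthelot-Lorentz combining rules are the arithmetic/geometric means", {
  cr <- lorentz_berthelot(2.89, 3.34, 206.74, 192.72)
  expect_equal(cr$sigma_ab, (2.89 + 3.34) / 2)
  expect_equal(cr$eps_ab, sqrt(206.74 * 192.72))
  # symmetric in the two components
  cr2 <- lorentz_berthelot(3.34, 2.89, 192.72, 206.74)
  expect_equal(cr$sigma_ab, cr2$sigma_ab)
  expect_equal(cr$eps_ab, cr2$eps_ab)
  expect_error(lorentz_berthelot(0, 1, 1, 1), "positive")
})

test_that("copolymer segment numbers scale linearly with molar mass", {
  expect_equal(copolymer_segments(1000, "EO"), 52)
  expect_equal(copolymer_segments(1000, "PO"), 37)
  expect_equal(copolymer_segments(0, "EO"), 0)
  # linearity
  expect_equal(copolymer_segments(8350, "EO"), 8.35 * copolymer_segments(1000, "EO"))
  expect_error(copolymer_segments(-1, "EO"), ">= 0")
})

test_that("poloxamer segment parameters interpolate between the pure groups", {
  pure_eo <- poloxamer_segments(1000, 1)
  expect_equal(pure_eo$m_seg, 52)
  expect_equal(pure_eo$sigma, 2.89)
  expect_equal(pure_eo$u_over_k, 206.74)
  pure_po <- poloxamer_segments(1000, 0)
  expect_equal(pure_po$m_seg, 37)
  expect_equal(pure_po$sigma, 3.34)
  mix <- poloxamer_segments(8350, 0.8)
  expect_gt(mix$sigma, pure_eo$sigma)
  expect_lt(mix$sigma, pure_po$sigma)
  expect_error(poloxamer_segments(1000, 1.2), "\\[0, 1\\]")
})

test_that("surface tension is positive for a sparingly soluble drug", {
  # itraconazole-like record: very low aqueous solubility
  gamma <- surface_tension(298.15, 1.27e6 * 705.64 / 0.000394, 705.64, 1e-9)
  expect_gt(gamma, 0)
  # raising the solubility lowers the surface tension
  gamma2 <- surface_tension(298.15, 1.27e6 * 705.64 / 0.000394, 705.64, 1e-6)
  expect_lt(gamma2, gamma)
  # at s0 = 55.6 * exp(-5) the bracket vanishes exactly
  g0 <- surface_tension(298.15, 2e9, 705.64, 55.6 * exp(-5))
  expect_equal(g0, 0, tolerance = 1e-12)
  expect_error(surface_tension(298.15, 2e9, 705.64, 0), "s0")
})

test_that("surface Gibbs term decays as 1/r for large particles and flips sign below C", {
  vm <- 0.000394
  gamma <- 0.02
  C <- 1.5 * (vm / 6.02214076e23)^(1 / 3)
  g_large <- gibbs_surface(gamma, vm, 1e-6)
  g_larger <- gibbs_surface(gamma, vm, 2e-6)
  expect_gt(g_large, g_larger)          # decreasing in r
  expect_gt(g_large, 0)
  # exactly zero at r = C
  expect_equal(gibbs_surface(gamma, vm, C), 0, tolerance = 1e-12)
  expect_error(gibbs_surface(gamma, vm, 0), "radius")
})

test_that("interfacial Gibbs term is linear in 1/r and in the stabilizer density", {
  api <- api_record("API", 705.64, 0.000394, 1e-9,
                    segment_params(25, 3.5, 250), 5e-10)
  stab <- stabilizer_record("S", 8350, segment_params(418, 2.89, 206.74), 951)
  g1 <- gibbs_interface(api, stab, 0.02, api$vm, 1e-7)
  g2 <- gibbs_interface(api, stab, 0.02, api$vm, 2e-7)
  expect_equal(g1, 2 * g2, tolerance = 1e-12)
  stab2 <- stab; stab2$density <- 2 * stab$density
  expect_equal(gibbs_interface(api, stab2, 0.02, api$vm, 1e-7), 2 * g1,
               tolerance = 1e-12)
  # more segments per chain dilute the per-chain contribution
  stab3 <- stab; stab3$segments$m_seg <- 2 * stab$segments$m_seg
  expect_equal(gibbs_interface(api, stab3, 0.02, api$vm, 1e-7), g1 / 2,
               tolerance = 1e-12)
})

test_that("solubility enhancement is exp(GEE/RT)", {
  expect_equal(solubility_enhancement(0, 298.15), 1)
  R <- 8.314462618
  expect_equal(solubility_enhancement(R * 298.15, 298.15), exp(1))
  expect_gt(solubility_enhancement(1000, 298.15), 1)
  expect_lt(solubility_enhancement(-1000, 298.15), 1)
  expect_error(solubility_enhancement(0, -1), "temperature")
})

test_that("gibbs_energy assembles a consistent assessment", {
  api <- api_record("API", 705.64, 0.000394, 1e-9,
                    segment_params(25, 3.5, 250), 5e-10)
  stab <- stabilizer_record("S", 8350, segment_params(418, 2.89, 206.74), 951)
  g <- gibbs_energy(api, stab, 298.15, 1e-7)
  expect_s3_class(g, "gibbs_result")
  expect_equal(g$gee, g$gms + g$gmi)
  expect_equal(g$k_ratio, solubility_enhancement(g$gee, 298.15))
  expect_output(print(g), "GEE")
})

test_that("rank_stabilizers selects the largest Gmi and breaks ties by name", {
  r <- rank_stabilizers(stabilizer_table()[, c("name", "gmi")])
  expect_equal(attr(r, "selected"), "Poloxamer-188")
  expect_equal(r$name[1], "Poloxamer-188")
  expect_true(r$selected[1])
  expect_false(any(r$selected[-1]))
  expect_equal(r$gmi, sort(r$gmi, decreasing = TRUE))
  # named-vector input and tie-breaking
  r2 <- rank_stabilizers(c(b = 1, a = 1, c = 0.5))
  expect_equal(attr(r2, "selected"), "a")
  expect_error(rank_stabilizers(data.frame(name = character(), gmi = numeric())),
               "empty")
  expect_error(rank_stabilizers(data.frame(foo = 1)), "name")
})

test_that("property_table interpolates linearly and refuses extrapolation", {
  f <- property_table(c(280, 300, 320), c(1000, 996, 988))
  expect_equal(f(300), 996)
  expect_equal(f(290), 998)  # linear midpoint
  expect_error(f(279), "outside")
  expect_error(property_table(c(300, 300), c(1, 2)), "increasing")
})

test_that("materials round-trip through YAML and drive the ranking", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    api = list(name = "API", mr = 705.64, vm = 0.000394, s0 = 1e-9,
               segments = list(m_seg = 25, sigma = 3.5, u_over_k = 250),
               delta_interlayer = 5e-10),
    stabilizers = list(
      list(name = "A", mw = 8350, density = 951, gmi_reference = 0.0056,
           segments = list(m_seg = 418, sigma = 2.89, u_over_k = 206.74)),
      list(name = "B", mw = 9840, density = 954, gmi_reference = 0.0039,
           segments = list(m_seg = 480, sigma = 2.93, u_over_k = 205.27)))),
    path)
  mats <- read_materials(path)
  expect_s3_class(mats$api, "api_record")
  expect_length(mats$stabilizers, 2)
  expect_equal(mats$stabilizers[[1]]$gmi_reference, 0.0056)
  ranking <- rank_stabilizers(data.frame(
    name = vapply(mats$stabilizers, `[[`, "", "name"),
    gmi = vapply(mats$stabilizers, `[[`, 0, "gmi_reference")))
  expect_equal(attr(ranking, "selected"), "A")
  out <- tempfile(fileext = ".csv")
  write_ranking_csv(ranking, out, records = mats$stabilizers)
  back <- read.csv(out)
  expect_equal(back$density[1], 951)
  expect_error(read_materials("no/such/file.yaml"), "not found")
})
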