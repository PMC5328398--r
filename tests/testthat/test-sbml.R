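# SBML subset and parameter-table interchange.

test_that("a toy model round-trips through SBML structurally intact", {
  tc <- make_toy_chain(3, forms = c("mm", "ma"), feed = 1, vmax = 3,
                       km = 0.8, k = 2)
  path <- tempfile(fileext = ".xml")
  write_sbml_model(tc$model, path)
  back <- read_sbml_model(path)
  expect_equal(back$species$id, tc$model$species$id)
  expect_equal(back$species$conc, tc$model$species$conc)
  expect_equal(names(back$reactions), names(tc$model$reactions))
  expect_equal(sort(names(back$params)), sort(names(tc$model$params)))
  expect_equal(back$params[names(tc$model$params)], tc$model$params)
  expect_equal(back$S, tc$model$S)
  # rate laws evaluate identically
  x <- setNames(tc$model$species$conc, tc$model$species$id)
  expect_equal(evaluate_rates(back, x), evaluate_rates(tc$model, x),
               tolerance = 1e-12)
})

test_that("the reference instance round-trips through SBML", {
  m <- ref_model()
  path <- tempfile(fileext = ".xml")
  write_sbml_model(m, path)
  back <- read_sbml_model(path)
  expect_equal(nrow(back$species), 62L)
  expect_equal(length(back$reactions), 68L)
  expect_equal(back$species$boundary, m$species$boundary)
  x <- setNames(m$species$conc, m$species$id)
  expect_equal(evaluate_rates(back, x), evaluate_rates(m, x), tolerance = 1e-9)
})

test_that("a reaction without a kinetic law is rejected by name", {
  tc <- make_toy_chain(2)
  path <- tempfile(fileext = ".xml")
  write_sbml_model(tc$model, path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  kl <- xml2::xml_find_first(doc, "//reaction[@id='STEP1']/kineticLaw")
  xml2::xml_remove(kl)
  path2 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc, path2)
  expect_error(read_sbml_model(path2), "STEP1.*no kinetic law")
})

test_that("unsupported SBML constructs are rejected, not ignored", {
  tc <- make_toy_chain(2)
  path <- tempfile(fileext = ".xml")
  write_sbml_model(tc$model, path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  md <- xml2::xml_find_first(doc, "//model")
  xml2::xml_add_child(md, "listOfEvents")
  path2 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc, path2)
  expect_error(read_sbml_model(path2), "listOfEvents")
})

test_that("build_reference_model reads the packaged parameter table", {
  m <- ref_model()
  path <- tempfile(fileext = ".tsv")
  write_parameter_table(m, path)
  back <- build_reference_model(path)
  expect_equal(length(back$reactions), 68L)
  expect_equal(nrow(back$species), 62L)
  cen <- interaction_census(back)
  expect_equal(cen$modifier_only, 34L)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  # the rebuilt model reproduces the reference steady state
  st <- steady_state(back)
  expect_true(st$converged)
  expect_equal(unname(st$fluxes["GROWTH"] * 3600), 0.1, tolerance = 1e-4)
})

test_that("missing or empty parameter sources raise informative errors", {
  expect_error(build_reference_model(tempfile()), "not found")
  empty <- tempfile(fileext = ".tsv")
  writeLines("scope\tid\tparameter\tvalue\tunit", empty)
  expect_error(build_reference_model(empty), "empty|missing")
  partial <- tempfile(fileext = ".tsv")
  writeLines(c("scope\tid\tparameter\tvalue\tunit",
               "reaction\tPGI\tVmax\t1\tmM/s"), partial)
  expect_error(build_reference_model(partial), "missing")
})

test_that("write_results produces TSV/JSON plus a manifest", {
  dir <- tempfile()
  out <- list(matrix_out = matrix(1:4, 2, dimnames = list(c("a", "b"), c("x", "y"))),
              summary = list(alpha = 1.5, seed = 7))
  write_results(out, config = list(seed = 7, n = 10), dir = dir)
  expect_true(file.exists(file.path(dir, "matrix_out.tsv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$config$seed, 7L)
  back <- read_tsv_matrix(file.path(dir, "matrix_out.tsv"))
  expect_equal(back$x, c(1L, 2L))
})

test_that("the packaged parameter table rebuilds the reference instance", {
  path <- system.file("extdata", "ecoli_synthetic_params.tsv",
                      package = "colikin")
  expect_true(nzchar(path))
  m <- build_reference_model(path)
  expect_equal(length(m$reactions), 68L)
  expect_equal(m$params, ref_model()$params, tolerance = 1e-10)
})
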