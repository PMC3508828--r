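test_that("SBML export/import round-trips every default model", {
  td <- withr::local_tempdir()
  for (tp in c("M1", "M4")) for (sch in c("K1", "K2", "K2_QSS")) {
    m <- default_model(tp, sch, "PSEQ")
    f1 <- file.path(td, "a.xml"); f2 <- file.path(td, "b.xml")
    export_sbml(m, f1)
    m2 <- import_sbml(f1)
    expect_equal(m2$topology$name, tp)
    expect_equal(m2$scheme, sch)
    expect_equal(m2$sequestration, "PSEQ")
    expect_equal(list_species(m2), list_species(m))
    # byte-stable idempotence
    export_sbml(m2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
  # exported K2 document carries the full species inventory
  m <- default_model("M1", "K2", "USEQ")
  f <- file.path(td, "m1.xml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level2/version4")
  expect_length(xml2::xml_find_all(doc, ".//s:species", ns), 22L)
})

test_that("an imported model simulates identically to the native one", {
  td <- withr::local_tempdir()
  m <- default_model("M3", "K2", "PSEQ")
  f <- file.path(td, "m3.xml")
  export_sbml(m, f)
  m2 <- import_sbml(f)
  prot <- signal_protocol(10)
  t1 <- simulate_cascade(m, prot, 1000, n_out = 10)
  t2 <- simulate_cascade(m2, prot, 1000, n_out = 10)
  expect_equal(t1$species, t2$species, tolerance = 1e-6)
})

test_that("SBML import reports structural problems explicitly", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.xml")
  writeLines("<sbml><model><oops>", bad)
  expect_error(import_sbml(bad), "parse failure")
  expect_error(import_sbml(file.path(td, "missing.xml")), "no such file")

  # deleting one reaction from a K2 export is caught with its name
  m <- default_model("M1", "K2", "USEQ")
  f <- file.path(td, "m1.xml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level2/version4")
  victim <- xml2::xml_find_first(
    doc, ".//s:reaction[@id='cat__Phos1__MKKK_P']", ns)
  xml2::xml_remove(victim)
  f_cut <- file.path(td, "cut.xml")
  xml2::write_xml(doc, f_cut)
  expect_error(import_sbml(f_cut), "cat__Phos1__MKKK_P")

  # a file following the M<i>_K<j>_<SEQ> stem convention imports without
  # the package annotation
  f_stem <- file.path(td, "M2_K1_USEQ.xml")
  export_sbml(default_model("M2", "K1", "USEQ"), f_stem)
  doc <- xml2::read_xml(f_stem)
  xml2::xml_remove(xml2::xml_find_first(doc, ".//*[name()='annotation']"))
  xml2::write_xml(doc, f_stem)
  m2 <- import_sbml(f_stem)
  expect_equal(m2$topology$name, "M2")
  expect_equal(m2$scheme, "K1")
})

test_that("parameter files load, validate and report offending keys", {
  td <- withr::local_tempdir()
  jf <- file.path(td, "p.json")
  jsonlite::write_json(list(
    concentrations = list(MKKK_total = 50, MKK_total = 600, MK_total = 600,
                          Phos1_total = 80, Phos2_total = 80, Sig = 5),
    k1_parameters = as.list(unclass(reference_parameters("M2", "K1")$params))),
    jf, auto_unbox = TRUE, digits = NA)
  cfg <- read_parameter_file(jf, "M2")
  expect_s3_class(cfg$concentrations, "cascade_concentrations")
  expect_equal(cfg$concentrations$MKKK_total, 50)
  expect_s3_class(cfg$k1_parameters, "k1_parameters")

  yf <- file.path(td, "p.yaml")
  writeLines(c("concentrations:", "  MKKK_total: 100", "  MKK_total: 1200",
               "  MK_total: 1200", "  Phos1_total: 150",
               "  Phos2_total: 150", "  Sig: 10"), yf)
  cfg2 <- read_parameter_file(yf, "M2")
  expect_equal(cfg2$concentrations$Sig, 10)

  bad <- file.path(td, "bad.json")
  jsonlite::write_json(list(concentraitons = list(Sig = 1)), bad,
                       auto_unbox = TRUE)
  expect_error(read_parameter_file(bad, "M2"), "concentraitons")
  incomplete <- file.path(td, "inc.json")
  jsonlite::write_json(list(k1_parameters = list(k1 = 1)), incomplete,
                       auto_unbox = TRUE)
  expect_error(read_parameter_file(incomplete, "M2"), "missing K1")
})

test_that("the command line writes reproducible tidy results", {
  td <- withr::local_tempdir()
  args <- c("robustness", "--model", "M2", "--scheme", "K1", "--seq",
            "USEQ", "--vary", "phosphatases", "--n", "40", "--seed", "1",
            "--out-dir", td)
  expect_equal(cascade_cli(args), 0L)
  csv <- file.path(td, "robustness_M2_K1_USEQ_phosphatases.csv")
  cfg <- file.path(td, "robustness_M2_K1_USEQ_phosphatases_config.json")
  expect_true(file.exists(csv) && file.exists(cfg))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 40L)
  expect_named(tab, c("simulation", "tpv", "output_ratio"))
  meta <- jsonlite::read_json(cfg)
  expect_equal(meta$seed, 1L)
  expect_lte(meta$robustness_coefficient, 0)
  expect_true(!is.null(meta$package_version))

  # identical run, identical bytes
  first <- readLines(csv)
  expect_equal(cascade_cli(args), 0L)
  expect_identical(readLines(csv), first)

  # usage errors exit non-zero
  expect_equal(suppressMessages(cascade_cli(c("simulate", "--model", "Mx"))),
               1L)
  expect_equal(suppressMessages(cascade_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(cascade_cli(character(0))), 1L)
})

test_that("export-sbml subcommand produces an importable document", {
  td <- withr::local_tempdir()
  out <- file.path(td, "model.xml")
  expect_equal(suppressMessages(cascade_cli(
    c("export-sbml", "--model", "M4", "--scheme", "K2", "--seq", "PSEQ",
      "--out", out))), 0L)
  m <- import_sbml(out)
  expect_equal(m$topology$name, "M4")
  expect_equal(m$sequestration, "PSEQ")
})
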