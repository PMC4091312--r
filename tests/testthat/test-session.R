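test_that("configurations round-trip through XML exactly", {
  dir <- withr::local_tempdir()
  sur <- make_surrogate(surrogate_case("uc2_synapse_vc"), dir = dir)
  cfg <- sur$config
  path <- file.path(dir, "roundtrip.xml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$data, cfg$data)
  expect_equal(back$parameters, cfg$parameters)
  expect_equal(back$protocol, cfg$protocol)
  expect_equal(back$cost, cfg$cost)
  expect_equal(back$optimizer[order(names(back$optimizer))],
               cfg$optimizer[order(names(cfg$optimizer))])
  expect_equal(back$backend$id, cfg$backend$id)
  expect_equal(back$backend$fixed$spike_times, cfg$backend$fixed$spike_times)
  expect_equal(back$output_dir, cfg$output_dir)
})

test_that("strict validation names missing, unknown and invalid tags", {
  dir <- withr::local_tempdir()
  sur <- make_surrogate(surrogate_case("uc2_synapse_vc"), dir = dir)
  path <- file.path(dir, "config_uc2_synapse_vc.xml")

  mangle <- function(fun) {
    doc <- xml2::read_xml(path)
    fun(doc)
    p2 <- file.path(dir, "mangled.xml")
    xml2::write_xml(doc, p2)
    p2
  }
  # missing required tag, named in the error
  p <- mangle(function(d) xml2::xml_remove(
    xml2::xml_find_first(d, "//parameter[1]/lower")))
  expect_error(read_config(p), "<lower>")
  # unknown tag, named in the error
  p <- mangle(function(d) xml2::xml_add_child(
    xml2::xml_find_first(d, "//optimizer"), "frobnicate"))
  expect_error(read_config(p), "<frobnicate>")
  set_text <- function(xpath, value) function(d) {
    node <- xml2::xml_find_first(d, xpath)
    xml2::xml_set_text(node, value)
  }
  # invalid algorithm id, with the valid ids listed
  p <- mangle(set_text("//algorithm", "EO2"))
  expect_error(read_config(p), "EO, SA, NM, LBFGSB")
  # invalid feature id
  p <- mangle(set_text("//term/feature", "mse3"))
  expect_error(read_config(p), "valid ids")
  # non-numeric value
  p <- mangle(set_text("//protocol/tstop", "soon"))
  expect_error(read_config(p), "not a number")
  # referenced data file must exist at load time
  p <- mangle(set_text("//data/path", "/nonexistent/target.txt"))
  expect_error(read_config(p), "does not exist")
})

test_that("a full session run produces coherent artifacts and reproduces exactly", {
  dir <- withr::local_tempdir()
  sur <- make_surrogate(surrogate_case("uc2_synapse_vc"), dir = dir)
  cfg_path <- file.path(dir, "config_uc2_synapse_vc.xml")
  out1 <- file.path(dir, "run1")
  fit <- run_session(cfg_path, seed = 3, generations = 8, output_dir = out1)
  arts <- attr(fit, "artifacts")
  for (a in c("best_trace", "figure", "report", "config", "summary"))
    expect_true(file.exists(arts[[a]]))
  # the best-trace file holds the fitted trace set
  bt <- read_traces(arts$best_trace, "current", "nA", fit$protocol$dt)
  expect_equal(bt$traces[[1]]$values, fitted(fit)$traces[[1]]$values,
               tolerance = 1e-8)
  # the HTML report prints the fitted parameters at display precision
  html <- paste(readLines(arts$report), collapse = "\n")
  for (p in signif(coef(fit), 8))
    expect_match(html, substr(sprintf("%.8g", p), 1, 6), fixed = TRUE)
  # per-feature breakdown re-weights to the reported total
  expect_equal(sum(fit$weights * fit$per_feature), fit$best_fitness,
               tolerance = 1e-9)
  # byte-identical re-run from the same config and seed
  out2 <- file.path(dir, "run2")
  fit2 <- run_session(cfg_path, seed = 3, generations = 8, output_dir = out2)
  expect_identical(readLines(file.path(out1, "result.txt")),
                   readLines(file.path(out2, "result.txt")))
  # the saved config re-runs to the same best fitness
  fit3 <- run_session(file.path(out1, "config_saved.xml"), seed = 3,
                      generations = 8, output_dir = file.path(dir, "run3"))
  expect_identical(fit3$best_fitness, fit$best_fitness)
  # a missing data file fails at the load stage
  cfg <- read_config(cfg_path)
  cfg$data$path <- file.path(dir, "gone.txt")
  expect_error(run_session(cfg, artifacts = FALSE), "not found")
})

test_that("a session recovers the synaptic parameters from its XML config", {
  dir <- withr::local_tempdir()
  sur <- make_surrogate(surrogate_case("uc2_synapse_vc"), dir = dir)
  fit <- run_session(file.path(dir, "config_uc2_synapse_vc.xml"), seed = 1,
                     output_dir = file.path(dir, "out"))
  rel <- abs(coef(fit) - sur$true_params) / sur$true_params
  expect_true(all(rel < 0.05))
})

test_that("a user function file maps abstract to backend parameters in a session", {
  dir <- withr::local_tempdir()
  sur <- make_surrogate(surrogate_case("uc1_hh"), dir = dir)
  uf <- file.path(dir, "user_fun.R")
  writeLines(c(
    "user_mapping <- function(p) {",
    "  c(gna = unname(p[['scale']]) * 0.12,",
    "    gk = unname(p[['scale']]) * 0.036,",
    "    gl = unname(p[['scale']]) * 3e-4)",
    "}"), uf)
  cfg <- sur$config
  cfg$backend$user_fun <- uf
  cfg$parameters <- list(parameter_spec("scale", 0.5, 2))
  fit <- run_session(cfg, seed = 2, generations = 5, artifacts = FALSE)
  expect_named(coef(fit), "scale")
  # the best trace is the backend run at the mapped abstract parameter
  direct <- simulate_hh_step(
    c(gna = 0.12, gk = 0.036, gl = 3e-4) * coef(fit)[["scale"]],
    list(diam = 10, L = 100), fit$protocol)
  expect_identical(direct$traces[[1]]$values, fitted(fit)$traces[[1]]$values)
  # and the reported best fitness re-evaluates through the mapping hook
  expect_equal(fit$objective(coef(fit)), fit$best_fitness,
               tolerance = 1e-12)
})

test_that("fitted-model methods expose the usual modelling interface", {
  dir <- withr::local_tempdir()
  sur <- make_surrogate(surrogate_case("uc2_synapse_vc"), dir = dir)
  fit <- run_session(sur$config, seed = 5, generations = 6, artifacts = FALSE)
  expect_s3_class(fit, "neurofit")
  expect_named(coef(fit), c("tau1", "tau2", "weight", "delay"))
  expect_equal(dim(residuals(fit)),
               c(length(sur$target$traces[[1]]$values), 1L))
  resim <- simulate(fit)
  expect_equal(resim$traces[[1]]$values, fitted(fit)$traces[[1]]$values)
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("best fitness", out)))
  expect_true(any(grepl("per-feature", out)))
  pngf <- file.path(tempdir(), "p.png")
  grDevices::png(pngf)
  plot(fit, type = "fit"); plot(fit, type = "generations")
  plot(fit, type = "alleles")
  grDevices::dev.off()
  expect_true(file.exists(pngf))
})
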