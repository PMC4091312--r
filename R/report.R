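# Result artifacts: best-trace text file, figures, HTML report, reproducing
# config, and a machine-readable key=value summary. Artifact content is a
# pure function of the fit, so a re-run with the same config and seed
# produces byte-identical summaries.

write_artifacts <- function(fit, config, eps = FALSE) {
  out <- config$output_dir
  p <- list(best_trace = file.path(out, "best_trace.txt"),
            figure = file.path(out, "fit.png"),
            report = file.path(out, "report.html"),
            config = file.path(out, "config_saved.xml"),
            summary = file.path(out, "result.txt"))

  write_traces(fit$best_sim, p$best_trace)

  png(p$figure, width = 900, height = 500)
  plot(fit, type = "fit")
  dev.off()
  if (eps) {
    p$figure_eps <- file.path(out, "fit.eps")
    postscript(p$figure_eps, width = 9, height = 5, horizontal = FALSE,
               onefile = FALSE, paper = "special")
    plot(fit, type = "fit")
    dev.off()
  }

  write_config(config, p$config)
  writeLines(result_summary_lines(fit), p$summary)
  writeLines(report_html(fit, config), p$report)
  invisible(p)
}

result_summary_lines <- function(fit) {
  c(sprintf("algorithm = %s", fit$algorithm),
    sprintf("seed = %d", fit$seed),
    sprintf("n_evaluations = %d", fit$n_evaluations),
    sprintf("best_fitness = %.17g", fit$best_fitness),
    sprintf("param.%s = %.17g", names(fit$best_params), fit$best_params),
    sprintf("feature.%s = %.17g", names(fit$per_feature), fit$per_feature),
    sprintf("weight.%s = %.17g", names(fit$weights), fit$weights),
    sprintf("raw_mse = %.17g", raw_mse(fit)))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

report_html <- function(fit, config) {
  row <- function(...) paste0("<tr>", paste0("<td>", c(...), "</td>",
                                             collapse = ""), "</tr>")
  par_rows <- paste(vapply(seq_along(fit$best_params), function(i) {
    b <- fit$bounds[i, ]
    row(html_escape(names(fit$best_params)[i]), sprintf("%.6g", b[1L]),
        sprintf("%.6g", b[2L]), sprintf("%.8g", fit$best_params[i]))
  }, character(1)), collapse = "\n")
  feat_rows <- paste(vapply(names(fit$per_feature), function(f)
    row(html_escape(f), sprintf("%.4g", fit$weights[[f]]),
        sprintf("%.8g", fit$per_feature[[f]]),
        sprintf("%.8g", fit$weights[[f]] * fit$per_feature[[f]])),
    character(1)), collapse = "\n")
  c("<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'><title>Model fitting report</title>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px 8px}</style>",
    "</head><body>",
    "<h1>Model fitting report</h1>",
    "<h2>Settings</h2>",
    "<table>",
    row("backend", html_escape(fit$backend$id)),
    row("algorithm", html_escape(fit$algorithm)),
    row("seed", fit$seed),
    row("evaluations", fit$n_evaluations),
    row("traces", length(fit$target)),
    row("dt (ms)", sprintf("%g", fit$protocol$dt)),
    "</table>",
    "<h2>Final parameters</h2>",
    "<table><tr><th>parameter</th><th>lower</th><th>upper</th><th>fitted</th></tr>",
    par_rows,
    "</table>",
    "<h2>Error breakdown</h2>",
    sprintf("<p>Total fitness: <b>%.8g</b></p>", fit$best_fitness),
    "<table><tr><th>feature</th><th>weight</th><th>raw</th><th>weighted</th></tr>",
    feat_rows,
    "</table>",
    "<h2>Target vs. best trace</h2>",
    "<img src='fit.png' alt='target vs best trace' width='880'>",
    "</body></html>")
}
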