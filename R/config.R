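#' Assemble a full session configuration
#'
#' A session configuration ties together the target data description, the
#' simulation backend, the tunable parameters with their bounds, the
#' stimulation/recording protocol, the cost specification and the optimizer
#' settings. It is the in-memory equivalent of the XML configuration file
#' handled by [read_config()] / [write_config()].
#'
#' @param data List with `path`, `kind`, `unit`, `dt`, `n_traces` describing
#'   the target trace file.
#' @param backend List with `id` (one of `hh_step`, `synaptic_vc`, `adexp`,
#'   `external`) and optional `fixed` settings, `command`, `user_fun`.
#' @param parameters List of [parameter_spec()] objects (unique names).
#' @param protocol A [protocol_spec()].
#' @param cost An [cost_spec()].
#' @param optimizer Named list of [optimizer_settings()] arguments (without
#'   `bounds`, which are derived from `parameters`).
#' @param output_dir Directory that [run_session()] writes artifacts to.
#' @return An object of class `nf_config`.
#' @export
session_config <- function(data, backend, parameters, protocol, cost,
                           optimizer, output_dir = ".") {
  stopifnot(inherits(protocol, "nf_protocol"), inherits(cost, "nf_cost_spec"))
  if (!length(parameters) ||
      !all(vapply(parameters, inherits, logical(1), "nf_param")))
    stop("'parameters' must be a non-empty list of parameter_spec objects")
  nms <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("parameter names must be unique")
  if (!backend$id %in% c("hh_step", "synaptic_vc", "adexp", "external"))
    stop("unknown backend id '", backend$id, "'")
  structure(list(data = data, backend = backend, parameters = parameters,
                 protocol = protocol, cost = cost, optimizer = optimizer,
                 output_dir = output_dir),
            class = "nf_config")
}

fmt_num <- function(x) sprintf("%.17g", x)
fmt_vec <- function(x) paste(fmt_num(x), collapse = " ")

xml_add_kv <- function(node, values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (is.null(v)) next
    ch <- xml2::xml_add_child(node, nm)
    xml2::xml_text(ch) <- if (is.numeric(v)) fmt_vec(v)
      else if (is.logical(v)) tolower(as.character(v))
      else as.character(v)
  }
  node
}

#' Write a session configuration as XML
#'
#' Every option has its own XML tag under a versioned `<settings>` root, so
#' that a saved configuration reproduces the optimization run exactly
#' (together with the seed).
#'
#' @param config An [session_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nf_config"))
  doc <- xml2::xml_new_root("settings", version = "1")
  xml_add_kv(xml2::xml_add_child(doc, "data"), config$data)
  bk <- xml2::xml_add_child(doc, "backend")
  xml_add_kv(bk, config$backend[setdiff(names(config$backend), "fixed")])
  if (!is.null(config$backend$fixed) && length(config$backend$fixed))
    xml_add_kv(xml2::xml_add_child(bk, "fixed"), config$backend$fixed)
  ps <- xml2::xml_add_child(doc, "parameters")
  for (p in config$parameters)
    xml_add_kv(xml2::xml_add_child(ps, "parameter"),
               list(name = p$name, lower = p$lower, upper = p$upper,
                    initial = p$initial))
  pr <- config$protocol
  xml_add_kv(xml2::xml_add_child(doc, "protocol"),
             list(mode = pr$mode, stim_kind = pr$stim_kind,
                  amplitudes = pr$amplitudes, delay = pr$delay,
                  duration = pr$duration, record = pr$record,
                  tstop = pr$tstop, dt = pr$dt, v_init = pr$v_init,
                  waveform_path = attr(pr, "waveform_path")))
  co <- xml2::xml_add_child(doc, "cost")
  for (f in names(config$cost$terms))
    xml_add_kv(xml2::xml_add_child(co, "term"),
               list(feature = f, weight = config$cost$terms[[f]]))
  xml_add_kv(co, list(spike_threshold = config$cost$spike_threshold,
                      exclusion_halfwidth = config$cost$exclusion_halfwidth,
                      stim_window = config$cost$stim_window,
                      pptd_bins = config$cost$pptd_bins,
                      normalize_weights = config$cost$normalize_weights,
                      ahp_mode = config$cost$ahp_mode))
  op <- xml2::xml_add_child(doc, "optimizer")
  o <- config$optimizer
  xml_add_kv(op, o[setdiff(names(o), c("sa", "nm", "lbfgsb"))])
  for (sub in c("sa", "nm", "lbfgsb"))
    if (!is.null(o[[sub]]))
      xml_add_kv(xml2::xml_add_child(op, sub), o[[sub]])
  od <- xml2::xml_add_child(doc, "output_dir")
  xml2::xml_text(od) <- config$output_dir
  xml2::write_xml(doc, path)
  invisible(path)
}

xml_kv <- function(node, allowed, required = character(), context = "") {
  kids <- xml2::xml_children(node)
  nms <- xml2::xml_name(kids)
  unknown <- setdiff(nms, allowed)
  if (length(unknown))
    stop("unknown tag(s) in <", context, ">: ",
         paste0("<", unknown, ">", collapse = ", "))
  miss <- setdiff(required, nms)
  if (length(miss))
    stop("missing required tag(s) in <", context, ">: ",
         paste0("<", miss, ">", collapse = ", "))
  out <- lapply(kids, xml2::xml_text)
  names(out) <- nms
  out
}

num1 <- function(x, tag) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v))
    stop("value of <", tag, "> is not a number: '", x, "'")
  v
}
numv <- function(x, tag) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(x), "\\s+")[[1L]]))
  if (!length(v) || anyNA(v))
    stop("value of <", tag, "> is not a numeric list: '", x, "'")
  v
}
bool1 <- function(x, tag) {
  if (!tolower(x) %in% c("true", "false"))
    stop("value of <", tag, "> must be 'true' or 'false'")
  tolower(x) == "true"
}

#' Read a session configuration from XML
#'
#' Strict counterpart of [write_config()]: unknown tags are rejected by
#' name, missing required tags are reported by name, and enumerated values
#' (backend ids, algorithm ids, feature ids) are validated against the known
#' lists at load time rather than during the run. `read_config()` after
#' [write_config()] is the identity on all fields.
#'
#' @param path Path to the XML configuration.
#' @return An [session_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "settings")
    stop("config root element must be <settings>")
  top <- xml2::xml_children(doc)
  top_names <- xml2::xml_name(top)
  allowed <- c("data", "backend", "parameters", "protocol", "cost",
               "optimizer", "output_dir")
  unknown <- setdiff(top_names, allowed)
  if (length(unknown))
    stop("unknown tag(s) in <settings>: ",
         paste0("<", unknown, ">", collapse = ", "))
  miss <- setdiff(allowed, top_names)
  if (length(miss))
    stop("missing required tag(s) in <settings>: ",
         paste0("<", miss, ">", collapse = ", "))
  pick <- function(nm) top[[which(top_names == nm)[1L]]]

  d <- xml_kv(pick("data"), c("path", "kind", "unit", "dt", "n_traces"),
              c("path", "kind", "unit", "dt", "n_traces"), "data")
  data <- list(path = d$path, kind = d$kind, unit = d$unit,
               dt = num1(d$dt, "dt"), n_traces = as.integer(num1(d$n_traces, "n_traces")))
  if (!data$kind %in% c("voltage", "current"))
    stop("<kind> must be 'voltage' or 'current'")
  if (!file.exists(data$path))
    stop("target data file referenced by config does not exist: ", data$path)

  bnode <- pick("backend")
  b <- xml_kv(bnode, c("id", "command", "user_fun", "fixed"), "id", "backend")
  backend <- list(id = b$id)
  if (!backend$id %in% c("hh_step", "synaptic_vc", "adexp", "external"))
    stop("unknown <id> '", b$id, "'; valid backends: hh_step, synaptic_vc, ",
         "adexp, external")
  if (!is.null(b$command)) backend$command <- b$command
  if (!is.null(b$user_fun)) {
    if (!file.exists(b$user_fun))
      stop("user function file referenced by config does not exist: ", b$user_fun)
    backend$user_fun <- b$user_fun
  }
  fx <- xml2::xml_find_first(bnode, "./fixed")
  if (!inherits(fx, "xml_missing")) {
    kids <- xml2::xml_children(fx)
    fixed <- lapply(kids, function(k) {
      txt <- xml2::xml_text(k)
      v <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]))
      if (anyNA(v)) txt else v
    })
    names(fixed) <- xml2::xml_name(kids)
    backend$fixed <- fixed
  }

  pnodes <- xml2::xml_find_all(pick("parameters"), "./parameter")
  if (!length(pnodes)) stop("<parameters> must contain at least one <parameter>")
  parameters <- lapply(pnodes, function(pn) {
    p <- xml_kv(pn, c("name", "lower", "upper", "initial"),
                c("name", "lower", "upper"), "parameter")
    parameter_spec(p$name, num1(p$lower, "lower"), num1(p$upper, "upper"),
                   if (!is.null(p$initial)) num1(p$initial, "initial"))
  })

  pr <- xml_kv(pick("protocol"),
               c("mode", "stim_kind", "amplitudes", "delay", "duration",
                 "record", "tstop", "dt", "v_init", "waveform_path"),
               c("mode", "stim_kind", "record", "tstop", "dt", "v_init"),
               "protocol")
  waveform <- NULL
  if (!is.null(pr$waveform_path)) {
    wkind <- if (identical(pr$mode, "voltage_clamp")) "voltage" else "current"
    waveform <- read_traces(pr$waveform_path, wkind, canonical_unit(wkind),
                            num1(pr$dt, "dt"))$traces[[1L]]
  }
  protocol <- protocol_spec(
    mode = pr$mode, stim_kind = pr$stim_kind,
    amplitudes = if (!is.null(pr$amplitudes)) numv(pr$amplitudes, "amplitudes") else 0,
    delay = if (!is.null(pr$delay)) num1(pr$delay, "delay") else 0,
    duration = if (!is.null(pr$duration)) num1(pr$duration, "duration") else 0,
    waveform = waveform, record = pr$record,
    tstop = num1(pr$tstop, "tstop"), dt = num1(pr$dt, "dt"),
    v_init = num1(pr$v_init, "v_init"))
  if (!is.null(pr$waveform_path))
    attr(protocol, "waveform_path") <- pr$waveform_path

  cnode <- pick("cost")
  ckv <- xml_kv(cnode, c("term", "spike_threshold", "exclusion_halfwidth",
                         "stim_window", "pptd_bins", "normalize_weights",
                         "ahp_mode"),
                "term", "cost")
  tnodes <- xml2::xml_find_all(cnode, "./term")
  parsed <- lapply(tnodes, function(tn) {
    t <- xml_kv(tn, c("feature", "weight"), c("feature", "weight"), "term")
    if (!t$feature %in% cost_features)
      stop("unknown <feature> '", t$feature, "'; valid ids: ",
           paste(cost_features, collapse = ", "))
    list(feature = t$feature, weight = num1(t$weight, "weight"))
  })
  terms <- setNames(vapply(parsed, `[[`, numeric(1), "weight"),
                    vapply(parsed, `[[`, character(1), "feature"))
  cost <- cost_spec(
    terms,
    spike_threshold = if (!is.null(ckv$spike_threshold))
      num1(ckv$spike_threshold, "spike_threshold") else 0,
    exclusion_halfwidth = if (!is.null(ckv$exclusion_halfwidth))
      num1(ckv$exclusion_halfwidth, "exclusion_halfwidth") else 5,
    stim_window = if (!is.null(ckv$stim_window))
      numv(ckv$stim_window, "stim_window"),
    pptd_bins = if (!is.null(ckv$pptd_bins))
      num1(ckv$pptd_bins, "pptd_bins") else 64,
    normalize_weights = if (!is.null(ckv$normalize_weights))
      bool1(ckv$normalize_weights, "normalize_weights") else TRUE,
    ahp_mode = if (!is.null(ckv$ahp_mode)) ckv$ahp_mode else "squared_mean")

  onode <- pick("optimizer")
  o <- xml_kv(onode, c("algorithm", "seed", "start", "pop_size",
                       "generations", "mutation_rate", "mutation_sigma",
                       "blend_alpha", "sa", "nm", "lbfgsb"),
              "algorithm", "optimizer")
  if (!o$algorithm %in% c("EO", "SA", "NM", "LBFGSB"))
    stop("unknown <algorithm> '", o$algorithm,
         "'; valid ids: EO, SA, NM, LBFGSB")
  optimizer <- list(algorithm = o$algorithm)
  if (!is.null(o$seed)) optimizer$seed <- as.integer(num1(o$seed, "seed"))
  if (!is.null(o$start)) optimizer$start <- numv(o$start, "start")
  for (nm in c("pop_size", "generations"))
    if (!is.null(o[[nm]])) optimizer[[nm]] <- as.integer(num1(o[[nm]], nm))
  for (nm in c("mutation_rate", "mutation_sigma", "blend_alpha"))
    if (!is.null(o[[nm]])) optimizer[[nm]] <- num1(o[[nm]], nm)
  for (sub in c("sa", "nm", "lbfgsb")) {
    sn <- xml2::xml_find_first(onode, paste0("./", sub))
    if (!inherits(sn, "xml_missing")) {
      kids <- xml2::xml_children(sn)
      vals <- lapply(kids, function(k) num1(xml2::xml_text(k), xml2::xml_name(k)))
      names(vals) <- xml2::xml_name(kids)
      optimizer[[sub]] <- vals
    }
  }

  output_dir <- xml2::xml_text(pick("output_dir"))
  session_config(data, backend, parameters, protocol, cost, optimizer,
                 output_dir)
}
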