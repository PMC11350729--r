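# File formats: the '#'-header CSV dialect for traces / progress curves /
# titrations, YAML scheme serialization, and JSON reports.
#
# CSV dialect: '# key: value' metadata lines, then a comma-separated header
# and data rows ('.' decimal). The 'type' key selects the object read back.

#' Write a trace, progress curve or titration series to CSV
#'
#' Metadata travel in `# key: value` header lines; unknown keys are
#' preserved on read. Round-trips at full double precision.
#'
#' @param x An `sf_trace`, `sf_progress` or `sf_titration`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  meta <- list()
  if (inherits(x, "sf_trace")) {
    meta$type <- "trace"
    meta$t_dead <- attr(x, "t_dead")
    meta$observable <- attr(x, "observable")
    meta$sigma <- attr(x, "sigma")
    meta$mix <- attr(x, "mix")
    conc0 <- attr(x, "conc0")
    if (!is.null(conc0)) {
      meta$conc0 <- paste(names(conc0), signif(conc0, 15), sep = "=", collapse = ";")
    }
  } else if (inherits(x, "sf_progress")) {
    meta$type <- "progress"
    meta$E_tot_uM <- attr(x, "E_tot")
    meta$S0_uM <- attr(x, "S0")
    meta$mode <- attr(x, "mode")
    meta$ammonia <- attr(x, "ammonia")
    meta$delta_eps <- attr(x, "delta_eps")
  } else if (inherits(x, "sf_titration")) {
    meta$type <- "titration"
    meta$P0_uM <- attr(x, "P0")
    meta$ligand <- attr(x, "ligand")
    meta$co_conc_uM <- attr(x, "co_conc")
  } else {
    stop("unsupported object for the trace CSV dialect", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (!is.null(v) && !all(is.na(v))) {
      writeLines(paste0("# ", k, ": ", format(v, digits = 17)), con)
    }
  }
  df <- as.data.frame(x)
  writeLines(paste(names(df), collapse = ","), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a trace, progress curve or titration series from CSV
#'
#' Inverse of [write_trace_csv()]; the `type` metadata key decides the class
#' of the returned object. Malformed files fail with the offending line
#' number (non-increasing time) or the missing key.
#'
#' @param path Input file.
#' @return An `sf_trace`, `sf_progress` or `sf_titration`.
#' @examples
#' tr <- read_trace_csv(system.file("extdata", "example_transient.csv",
#'                                  package = "stopflow"))
#' tr
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(lines[ln], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[ln]))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(meta$type)) {
    stop("format error: missing required metadata key 'type'", call. = FALSE)
  }
  body_start <- if (length(meta_lines)) max(meta_lines) + 1 else 1
  df <- utils::read.csv(text = paste(lines[body_start:length(lines)],
                                     collapse = "\n"))
  num <- function(key, default = NA_real_) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  check_time <- function(tt, col) {
    bad <- which(diff(tt) <= 0)
    if (length(bad)) {
      stop("format error: non-increasing ", col, " at line ",
           body_start + bad[1] + 1, call. = FALSE)
    }
  }
  switch(meta$type,
    trace = {
      check_time(df$time, "time")
      conc0 <- NULL
      if (!is.null(meta$conc0)) {
        kv <- strsplit(strsplit(meta$conc0, ";")[[1]], "=")
        conc0 <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]),
                                        numeric(1)),
                                 vapply(kv, `[`, character(1), 1))
      }
      new_trace(df$time, df$signal, conc0 = conc0,
                t_dead = num("t_dead", 0),
                observable = meta$observable %||% "fluorescence",
                sigma = num("sigma"), mix = meta$mix %||% "")
    },
    progress = {
      check_time(df$time, "time")
      x <- tibble::tibble(time = df$time, absorbance = df$absorbance)
      class(x) <- c("sf_progress", class(x))
      attr(x, "E_tot") <- num("E_tot_uM")
      attr(x, "S0") <- num("S0_uM")
      attr(x, "mode") <- meta$mode %||% "multiple_turnover"
      attr(x, "ammonia") <- identical(meta$ammonia, "TRUE")
      attr(x, "delta_eps") <- num("delta_eps", 0.005637)
      if (identical(attr(x, "mode"), "control") && isTRUE(attr(x, "ammonia"))) {
        stop("format error: control curves must have ammonia: FALSE", call. = FALSE)
      }
      x
    },
    titration = {
      if (is.unsorted(df$conc)) {
        stop("format error: titration concentrations must be nondecreasing",
             call. = FALSE)
      }
      x <- tibble::as_tibble(df)
      class(x) <- c("sf_titration", class(x))
      attr(x, "P0") <- num("P0_uM")
      attr(x, "ligand") <- meta$ligand %||% "S"
      attr(x, "co_conc") <- num("co_conc_uM", 0)
      x
    },
    stop("format error: unknown type '", meta$type, "'", call. = FALSE))
}

#' Serialize a kinetic scheme to YAML (and back)
#'
#' The document records species (name, role, moiety counts), reactions
#' (reactants, products, rate-constant names) and the builtin id; reading it
#' back re-validates moiety balance.
#'
#' @param scheme A `kinetic_scheme`.
#' @param path Output / input file.
#' @return `scheme_to_yaml()`: `path`, invisibly. `scheme_from_yaml()`: a
#'   `kinetic_scheme`.
#' @export
scheme_to_yaml <- function(scheme, path) {
  doc <- list(
    builtin_id = scheme$builtin_id,
    species = lapply(seq_len(nrow(scheme$species)), function(i) {
      c(list(name = scheme$species$name[i], role = scheme$species$role[i]),
        as.list(scheme$moieties[i, ]))
    }),
    reactions = lapply(seq_len(nrow(scheme$reactions)), function(j) {
      list(reactants = as.list(scheme$reactions$reactants[[j]]),
           products = as.list(scheme$reactions$products[[j]]),
           kf_name = scheme$reactions$kf_name[j],
           kr_name = scheme$reactions$kr_name[j])
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname scheme_to_yaml
#' @export
scheme_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  species <- dplyr::bind_rows(lapply(doc$species, tibble::as_tibble))
  reactions <- tibble::tibble(
    reactants = lapply(doc$reactions, function(r) unlist(r$reactants)),
    products = lapply(doc$reactions, function(r) unlist(r$products)),
    kf_name = vapply(doc$reactions, `[[`, character(1), "kf_name"),
    kr_name = vapply(doc$reactions, function(r) r$kr_name %||% "", character(1)))
  sc <- new_kinetic_scheme(doc$builtin_id %||% "CUSTOM", species, reactions)
  sc
}

#' Write a JSON analysis report
#'
#' Serializes one or more fit results into a deterministic JSON document:
#' parameter tables with SEs, model/AICc information, verdicts, the package
#' version and a content hash of the inputs. Results are written in name
#' order; rerunning the same analysis reproduces the file byte-for-byte
#' apart from the timestamp field.
#'
#' @param results Named list of fit objects (`exp_fit`, `secondary_fit`,
#'   `mechanism_verdict`, `global_fit_result`, `mm_fit`, `titration_fit`,
#'   `synergy_report`, or plain lists/tibbles).
#' @param path Output file.
#' @param residual_dir Optional directory for per-trace residual CSVs from
#'   global fits.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, residual_dir = NULL) {
  if (length(results) == 0) stop("empty results: nothing to report", call. = FALSE)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("`results` must be a fully named list", call. = FALSE)
  }
  results <- results[order(names(results))]
  blocks <- lapply(results, report_block)
  doc <- list(
    software = paste0("stopflow ",
                      as.character(utils::packageVersion("stopflow"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    content_hash = report_hash(blocks),
    results = blocks)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(residual_dir)) {
    dir.create(residual_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results)) {
      r <- results[[nm]]
      if (inherits(r, "global_fit_result")) {
        for (i in seq_along(r$residuals)) {
          utils::write.csv(
            data.frame(time = r$traces[[i]]$time, residual = r$residuals[[i]]),
            file.path(residual_dir, sprintf("%s_trace%02d_residuals.csv", nm, i)),
            row.names = FALSE)
        }
      }
    }
  }
  invisible(path)
}

# cheap deterministic content hash (sum of character codes of the serialized
# blocks) - enough to tie a report to its inputs without extra dependencies
report_hash <- function(blocks) {
  s <- jsonlite::toJSON(blocks, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 251)) %% .Machine$integer.max)
}

report_block <- function(x) UseMethod("report_block")

#' @export
report_block.default <- function(x) x

#' @export
report_block.data.frame <- function(x) x

#' @export
report_block.exp_fit <- function(x) {
  list(kind = "exponential_fit", n_phases = x$n_phases,
       parameters = x$coef, rss = x$rss, aicc = x$aicc)
}

#' @export
report_block.secondary_fit <- function(x) {
  list(kind = "secondary_plot_fit", model = x$model, parameters = x$coef,
       rss = x$rss, aicc = x$aicc,
       identifiability_warning = x$identifiability_warning)
}

#' @export
report_block.mechanism_verdict <- function(x) {
  list(kind = "mechanism_verdict", classification = x$classification,
       delta_aicc = x$delta_aicc, threshold = x$threshold)
}

#' @export
report_block.global_fit_result <- function(x) {
  list(kind = "global_fit", parameters = x$coef,
       derived = derived_constants_fit(x),
       responses = x$responses, rss = x$rss, aicc = x$aicc,
       n_obs = x$n_obs, engine = x$engine, converged = x$converged)
}

#' @export
report_block.mm_fit <- function(x) {
  list(kind = "michaelis_menten", parameters = x$coef, E_tot = x$E_tot,
       rss = x$rss, identifiability_warning = x$identifiability_warning)
}

#' @export
report_block.titration_fit <- function(x) {
  list(kind = "titration_fit", model = x$model, parameters = x$coef,
       rss = x$rss, saturation_warning = x$saturation_warning)
}

#' @export
report_block.synergy_report <- function(x) {
  list(kind = "synergy", ratio = x$ratio, se = x$se,
       kd_binary = x$kd_binary, kd_ternary = x$kd_ternary,
       amp_ratio = x$amp_ratio, flag = x$flag)
}
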