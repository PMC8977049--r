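#' Read a multi-population cluster table
#'
#' Reads a CSV (or xlsx, when the readxl package is installed) file with
#' one row per cluster/study/site. The file must contain a column named
#' `positive` (observed number of test-positives) and a column named `n`
#' (number sampled); header matching is case-insensitive and
#' whitespace-trimmed, column order is irrelevant, and any further columns
#' (study labels, countries, years, ...) are carried along as metadata. A
#' `study` column, if present, labels the clusters; otherwise row numbers
#' do.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by file extension), `"csv"` or `"xlsx"`.
#' @return A validated tibble with at least the columns `study`,
#'   `positive`, `n`, classed `cluster_table`.
#' @export
read_cluster_table <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("File '%s' does not exist.", path),
                               call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx"
              else "csv"
  }
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("Reading spreadsheets requires the 'readxl' package.",
           call. = FALSE)
    }
    readxl::read_excel(path, .name_repair = "minimal")
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal")
  }
  validate_cluster_table(raw)
}

validate_cluster_table <- function(raw) {
  nms <- tolower(trimws(names(raw)))
  for (req in c("positive", "n")) {
    hits <- which(nms == req)
    if (length(hits) == 0L) {
      stop(sprintf("Required column '%s' is missing (found: %s).", req,
                   paste(names(raw), collapse = ", ")), call. = FALSE)
    }
    if (length(hits) > 1L) {
      stop(sprintf("Column '%s' appears %d times; headers must be unique.",
                   req, length(hits)), call. = FALSE)
    }
  }
  if (nrow(raw) < 1L) stop("The cluster table has no rows.", call. = FALSE)
  y <- raw[[which(nms == "positive")]]
  n <- raw[[which(nms == "n")]]
  check_count <- function(x, name) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x))) |
                   as.numeric(x) != round(as.numeric(x)) |
                   as.numeric(x) < 0)
    if (length(bad) > 0L) {
      stop(sprintf("Column '%s' must hold non-negative integers; bad row(s): %s.",
                   name, paste(bad, collapse = ", ")), call. = FALSE)
    }
    as.integer(x)
  }
  y <- check_count(y, "positive")
  n <- check_count(n, "n")
  bad <- which(n <= 0L)
  if (length(bad) > 0L) {
    stop(sprintf("Column 'n' must be positive; bad row(s): %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad <- which(y > n)
  if (length(bad) > 0L) {
    stop(sprintf("'positive' exceeds 'n' in row(s): %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  meta <- raw[, !(nms %in% c("positive", "n")), drop = FALSE]
  study <- if ("study" %in% tolower(trimws(names(meta)))) {
    as.character(meta[[which(tolower(trimws(names(meta))) == "study")[1]]])
  } else {
    as.character(seq_along(y))
  }
  out <- tibble::tibble(study = study, positive = y, n = n)
  extra <- meta[, tolower(trimws(names(meta))) != "study", drop = FALSE]
  out <- dplyr::bind_cols(out, extra)
  class(out) <- c("cluster_table", class(out))
  out
}

#' Per-cluster box-plot statistics
#'
#' Five-number summaries of the posterior draws of each cluster prevalence,
#' with Tukey whiskers: the box spans the quartiles, and each whisker ends
#' at the most extreme draw within 1.5 interquartile ranges of its
#' quartile.
#'
#' @param fit A `"true_multi"` [fit_prevalence()] result.
#' @param clusters Optional subset of cluster labels.
#' @return A tibble with columns `cluster`, `ymin`, `lower`, `middle`,
#'   `upper`, `ymax` (ggplot2's `geom_boxplot(stat = "identity")`
#'   aesthetics).
#' @export
cluster_boxplot_stats <- function(fit, clusters = NULL) {
  stopifnot(inherits(fit, "prev_fit"))
  if (fit$model$family != "true_multi") {
    stop("Box-plot statistics require a hierarchical ('true_multi') fit.",
         call. = FALSE)
  }
  clusters <- clusters %||% fit$clusters
  unknown <- setdiff(clusters, fit$clusters)
  if (length(unknown) > 0L) {
    stop(sprintf("Unknown cluster(s): %s.", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  purrr::map_dfr(clusters, function(cl) {
    x <- pooled_draws(fit, paste0("pi_t[", cl, "]"))
    q <- post_quantile(x, c(0.25, 0.5, 0.75))
    iqr <- q[3] - q[1]
    lo <- suppressWarnings(min(x[x >= q[1] - 1.5 * iqr]))
    hi <- suppressWarnings(max(x[x <= q[3] + 1.5 * iqr]))
    tibble::tibble(cluster = cl, ymin = lo, lower = q[1], middle = q[2],
                   upper = q[3], ymax = hi)
  })
}

#' Assemble a report bundle
#'
#' Collects everything the analysis report prints — the model and prior
#' selections (echoed with their hyperparameters and prior summaries), the
#' data digest, posterior summaries, threshold probabilities, per-cluster
#' box-plot statistics for hierarchical fits, and the convergence
#' diagnostics — in one object. Every number in the bundle is recomputable
#' from the exported draws plus the echoed specification.
#'
#' @param fit A [fit_prevalence()] result.
#' @param threshold Prevalence threshold for exceedance/freedom
#'   probabilities.
#' @return An object of class `prev_report`.
#' @export
build_report <- function(fit, threshold = 0.05) {
  stopifnot(inherits(fit, "prev_fit"))
  hier <- fit$model$family == "true_multi"
  prev_par <- if (hier) "mu" else if (fit$model$family == "true_single")
    "pi_t" else "pi_a"
  prior_echo <- prior_echo_table(fit$model)
  out <- list(
    family = fit$model$family,
    zero_inflated = fit$model$zero_inflated,
    config = fit$config,
    data = fit$data,
    priors = prior_echo,
    posterior = posterior_summary(fit),
    threshold = threshold,
    p_exceeds = prob_exceeds(fit, prev_par, threshold),
    prevalence_parameter = prev_par,
    diagnostics = mcmc_diagnostics(fit),
    densities = purrr::map_dfr(fit$parameters,
                               function(p) density_tables(fit, p)),
    cluster_boxplots = if (hier) cluster_boxplot_stats(fit) else NULL,
    freedom = if (hier) freedom_summaries(fit, threshold = threshold)
              else NULL,
    fit = fit)
  structure(out, class = "prev_report")
}

prior_echo_table <- function(model) {
  rows <- list()
  add <- function(name, prior) {
    if (is.null(prior)) return()
    s <- summarize_prior(prior)
    kind <- class(prior)[1]
    hp <- switch(kind,
                 beta_prior = c(prior$alpha, prior$beta),
                 gamma_prior = c(prior$shape, prior$rate),
                 point_mass = c(prior$value, NA_real_))
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(parameter = name, distribution = kind,
                     hyper1 = hp[1], hyper2 = hp[2]), s)
  }
  if (model$family == "true_multi") {
    add("mu", model$prevalence_prior$mu)
    add("psi", model$prevalence_prior$psi)
  } else {
    add(if (model$family == "true_single") "pi_t" else "pi_a",
        model$prevalence_prior)
  }
  add("se", model$se_prior)
  add("sp", model$sp_prior)
  if (model$zero_inflated) add("w", model$w_prior)
  dplyr::bind_rows(rows)
}

#' @export
print.prev_report <- function(x, ...) {
  cat(sprintf("Prevalence analysis report — %s%s\n", x$family,
              if (x$zero_inflated) " (zero-inflated)" else ""))
  cat(sprintf("Data: %d population(s), total n = %d, total positives = %d\n",
              nrow(x$data), sum(x$data$n), sum(x$data$positive)))
  cat("\nPriors:\n"); print(x$priors)
  cat("\nPosterior:\n"); print(x$posterior)
  cat(sprintf("\nP(%s > %g) = %.3f\n", x$prevalence_parameter, x$threshold,
              x$p_exceeds))
  cat("\nDiagnostics:\n"); print(x$diagnostics)
  invisible(x)
}

#' Export a completed run to plain-text files
#'
#' Writes three open, re-loadable artifacts into `directory`:
#' `input.csv` (the data), `model.json` (family, full-precision priors,
#' zero-inflation flag and MCMC configuration including the seed) and
#' `draws.csv` (all retained draws, one row per chain/iteration/parameter),
#' plus a convenience `summary.csv`. Re-loading the draws reproduces every
#' report number exactly, and re-fitting the exported model specification
#' with its recorded seed reproduces the draws themselves.
#'
#' @param fit A [fit_prevalence()] result or a [build_report()] bundle.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_run <- function(fit, directory) {
  if (inherits(fit, "prev_report")) fit <- fit$fit
  stopifnot(inherits(fit, "prev_fit"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("Cannot create directory '%s'.", directory),
                  call. = FALSE)
  }
  paths <- file.path(directory,
                     c("input.csv", "model.json", "draws.csv",
                       "summary.csv"))
  readr::write_csv(fit$data, paths[1])
  jsonlite::write_json(serialize_model(fit$model, fit$config), paths[2],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(posterior_draws(fit), paths[3])
  readr::write_csv(posterior_summary(fit), paths[4])
  invisible(paths)
}

# hyperparameters are stored as 17-significant-digit decimal strings so a
# JSON round trip is bit-exact and a re-fit reproduces the draws
num_exact <- function(x) sprintf("%.17g", x)

serialize_prior <- function(p) {
  if (is.null(p)) return(NULL)
  switch(class(p)[1],
         beta_prior = list(type = "beta", alpha = num_exact(p$alpha),
                           beta = num_exact(p$beta)),
         gamma_prior = list(type = "gamma", shape = num_exact(p$shape),
                            rate = num_exact(p$rate)),
         point_mass = list(type = "point_mass",
                           value = num_exact(p$value)))
}

deserialize_prior <- function(x) {
  if (is.null(x)) return(NULL)
  switch(x$type,
         beta = beta_prior(as.numeric(x$alpha), as.numeric(x$beta)),
         gamma = gamma_prior(as.numeric(x$shape), as.numeric(x$rate)),
         point_mass = point_mass(as.numeric(x$value)))
}

serialize_model <- function(model, config) {
  pp <- if (model$family == "true_multi") {
    list(mu = serialize_prior(model$prevalence_prior$mu),
         psi = serialize_prior(model$prevalence_prior$psi))
  } else {
    serialize_prior(model$prevalence_prior)
  }
  list(family = model$family,
       prevalence_prior = pp,
       se_prior = serialize_prior(model$se_prior),
       sp_prior = serialize_prior(model$sp_prior),
       zero_inflated = model$zero_inflated,
       w_prior = serialize_prior(model$w_prior),
       config = unclass(config))
}

#' Re-load an exported run
#'
#' Reads the files written by [export_run()] back into a `prev_fit`-shaped
#' object, so summaries, diagnostics and plots can be regenerated exactly
#' without re-running the sampler.
#'
#' @param directory Directory previously written by [export_run()].
#' @return A list with `fit` (a reconstructed `prev_fit`), `model` and
#'   `config`.
#' @export
import_run <- function(directory) {
  spec <- jsonlite::read_json(file.path(directory, "model.json"),
                              simplifyVector = FALSE)
  pp <- if (spec$family == "true_multi") {
    list(mu = deserialize_prior(spec$prevalence_prior$mu),
         psi = deserialize_prior(spec$prevalence_prior$psi))
  } else {
    deserialize_prior(spec$prevalence_prior)
  }
  model <- prev_model(spec$family, prevalence_prior = pp,
                      se_prior = deserialize_prior(spec$se_prior),
                      sp_prior = deserialize_prior(spec$sp_prior),
                      zero_inflated = isTRUE(spec$zero_inflated),
                      w_prior = deserialize_prior(spec$w_prior))
  cfg <- do.call(mcmc_config, spec$config)
  data <- as_count_data(readr::read_csv(file.path(directory, "input.csv"),
                                        show_col_types = FALSE))
  long <- readr::read_csv(file.path(directory, "draws.csv"),
                          show_col_types = FALSE)
  params <- unique(long$parameter)
  chains <- sort(unique(long$.chain))
  draws <- lapply(chains, function(ch) {
    sub <- long[long$.chain == ch, ]
    m <- vapply(params, function(p) sub$value[sub$parameter == p],
                numeric(sum(sub$parameter == params[1])))
    colnames(m) <- params
    m
  })
  fit <- structure(list(draws = draws, parameters = params, model = model,
                        data = data, config = cfg,
                        clusters = if (spec$family == "true_multi")
                          data$study else NULL),
                   class = "prev_fit")
  list(fit = fit, model = model, config = cfg)
}
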