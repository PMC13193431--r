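#' Parse a ";"-delimited band-radius field
#'
#' @param x character vector of ";"-joined radii.
#' @return list of numeric vectors (single numeric vector for length-1
#'   input).
#' @export
split_radii <- function(x) {
  out <- lapply(strsplit(x, ";", fixed = TRUE), as.numeric)
  if (length(out) == 1) out[[1]] else out
}

EDGE_TYPES <- c("opaque", "translucent", "unreadable", "birthmark_only")

#' Read and validate an ageing table CSV
#'
#' Reads the standard one-row-per-fish ageing schema (`fish_id`, `sex`,
#' `capture_date`, `dw_mm`, `vr_mm`, `edge_type`, `read1`, `band_radii_mm`;
#' optional `read2`, `read3`, `gear`, `region`). Rows failing validation
#' (non-positive sizes, unknown sex or edge type, unparseable date,
#' non-ascending radii, radii exceeding the centrum radius) are quarantined
#' with line-numbered reasons -- reported via warning and the
#' `"quarantine"` attribute -- never silently dropped.
#'
#' @param path CSV path.
#' @return validated data frame of specimens; quarantined rows (with a
#'   `reason` column) in `attr(, "quarantine")`.
#' @export
read_ageing_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("band_radii_mm" %in% names(raw))
    raw$band_radii_mm <- as.character(raw$band_radii_mm)
  if (nrow(raw) == 0) stop("empty input: ", path)
  need <- c("fish_id", "sex", "capture_date", "dw_mm", "vr_mm",
            "edge_type", "read1", "band_radii_mm")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))

  reasons <- character(nrow(raw))
  note <- function(i, why) reasons[i] <<- if (reasons[i] == "") why
    else paste(reasons[i], why, sep = "; ")
  for (i in seq_len(nrow(raw))) {
    if (!is.finite(raw$dw_mm[i]) || raw$dw_mm[i] <= 0)
      note(i, "non-positive disc width")
    if (!is.finite(raw$vr_mm[i]) || raw$vr_mm[i] <= 0)
      note(i, "non-positive vertebral radius")
    if (!raw$sex[i] %in% c("M", "F")) note(i, "unknown sex")
    if (!raw$edge_type[i] %in% EDGE_TYPES) note(i, "unknown edge type")
    if (is.na(as.Date(raw$capture_date[i], format = "%Y-%m-%d")))
      note(i, "unparseable capture date")
    radii <- suppressWarnings(as.numeric(
      strsplit(raw$band_radii_mm[i], ";", fixed = TRUE)[[1]]))
    if (length(radii) == 0 || anyNA(radii)) {
      note(i, "unparseable radii")
    } else {
      if (is.unsorted(radii, strictly = TRUE)) note(i, "non-ascending radii")
      if (is.finite(raw$vr_mm[i]) && any(radii > raw$vr_mm[i] + 1e-9))
        note(i, "radius exceeds centrum radius")
    }
  }
  bad <- reasons != ""
  quarantine <- raw[bad, , drop = FALSE]
  if (nrow(quarantine) > 0) {
    quarantine$line <- which(bad) + 1L  # header is line 1
    quarantine$reason <- reasons[bad]
    warning(sprintf("quarantined %d row(s): %s", nrow(quarantine),
                    paste(sprintf("line %d (%s)", quarantine$line,
                                  quarantine$reason),
                          collapse = "; ")))
  }
  ok <- raw[!bad, , drop = FALSE]
  if (nrow(ok) == 0) stop("no valid rows after validation")
  rownames(ok) <- NULL
  attr(ok, "quarantine") <- quarantine
  ok
}

#' Write an ageing table CSV
#'
#' @param fish specimen data frame (e.g. `simulate_population(...)$fish`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ageing_csv <- function(fish, path) {
  utils::write.csv(fish, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input path to an ageing CSV, a `synthetic_dataset`, or `NULL` to
#'   simulate from `sim`.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @param stages character vector of stages to run (subset of `"precision"`,
#'   `"edges"`, `"backcalc"`, `"growth"`, `"longevity"`, `"comparative"`).
#' @param families growth families to fit.
#' @param priors a [growth_priors()].
#' @param mcmc list of MCMC settings (`chains`, `warmup`, `iter`, `adapt`).
#' @param alpha significance level for the ANCOVA pooling decision.
#' @param force_split fit the DW-VR regression per sex regardless of the
#'   ANCOVA outcome.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir optional directory for CSV/JSON outputs and the run
#'   manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            stages = c("precision", "edges", "backcalc",
                                       "growth", "longevity", "comparative"),
                            families = growth_families,
                            priors = growth_priors(),
                            mcmc = list(chains = 4, warmup = 1000,
                                        iter = 3000, adapt = 1000),
                            alpha = 0.05, force_split = FALSE, seed = 1,
                            out_dir = NULL) {
  structure(list(input = input, sim = sim, stages = stages,
                 families = families, priors = priors, mcmc = mcmc,
                 alpha = alpha, force_split = force_split, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(report, name, deps, expr) {
  failed_dep <- deps[deps %in% names(report$errors)]
  if (length(failed_dep) > 0) {
    report$errors[[name]] <- paste("skipped: upstream stage failed:",
                                   paste(failed_dep, collapse = ", "))
    return(report)
  }
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) report$errors[[name]] <- conditionMessage(res)
  else report[[name]] <- res
  report
}

#' Run the full age-and-growth pipeline
#'
#' Chains every stage on one dataset: read adjudication, between-reading
#' precision, band-periodicity model selection, DW-VR regression with
#' ANCOVA sex pooling, body-proportional back-calculation, Bayesian growth
#' fits for each family and sex with model comparison and posterior sex
#' contrasts, theoretical longevity, and the cross-species comparative
#' statistics. A failed stage halts only the stages depending on it;
#' independent stages still run (failures are collected in `$errors`).
#' When `cfg$out_dir` is set, tabular outputs plus a machine-readable
#' manifest (seed, package version, config hash) are written there.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_report` with components `data`,
#'   `precision`, `age_bias`, `edges`, `dwvr`, `ancova`, `pairs`,
#'   `age_summary`, `growth` (per sex: fits and comparison), `contrasts`,
#'   `longevity`, `comparative`, `errors`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  report <- list(errors = list())

  # --- data ---------------------------------------------------------------
  if (is.null(cfg$input)) {
    sim <- cfg$sim; sim$seed <- cfg$seed
    ds <- simulate_double_reads(simulate_population(sim))
    fish <- ds$fish
    report$truth <- ds$truth
  } else if (inherits(cfg$input, "synthetic_dataset")) {
    fish <- cfg$input$fish
    report$truth <- cfg$input$truth
  } else {
    fish <- read_ageing_csv(cfg$input)
  }
  if (!"read2" %in% names(fish)) fish$read2 <- fish$read1
  fish$age <- adjudicate_reads(fish)
  report$data <- fish
  aged <- fish[!is.na(fish$age), , drop = FALSE]

  if ("precision" %in% cfg$stages) {
    report <- pipeline_stage(report, "precision", character(0),
                             precision_report(fish))
    report <- pipeline_stage(report, "age_bias", character(0),
                             age_bias(fish))
  }
  if ("edges" %in% cfg$stages) {
    report <- pipeline_stage(report, "edges", character(0),
                             select_edge_model(aggregate_edges(fish)))
  }
  if (any(c("backcalc", "growth") %in% cfg$stages)) {
    report <- pipeline_stage(report, "dwvr", character(0), fit_dw_vr(aged))
    report <- pipeline_stage(report, "ancova", character(0),
                             ancova_sex(aged, alpha = cfg$alpha))
    report <- pipeline_stage(report, "pairs", c("dwvr", "ancova"), {
      pooled <- !cfg$force_split &&
        (is.null(report$ancova) || isTRUE(report$ancova$pooled))
      if (pooled) back_calculate(aged, report$dwvr)
      else do.call(rbind, lapply(c("M", "F"), function(s) {
        sub <- aged[aged$sex == s, , drop = FALSE]
        back_calculate(sub, fit_dw_vr(sub))
      }))
    })
    report <- pipeline_stage(report, "age_summary", "pairs",
                             summarize_by_age(report$pairs, aged))
  }

  if ("growth" %in% cfg$stages) {
    report <- pipeline_stage(report, "growth", "pairs", {
      sexes <- intersect(c("M", "F"), unique(report$pairs$sex))
      out <- lapply(sexes, function(s) {
        obs <- build_growth_input(report$pairs, s)
        fits <- lapply(cfg$families, function(fam)
          growth_fit(dw ~ age, obs, family = fam, priors = cfg$priors,
                     chains = cfg$mcmc$chains, warmup = cfg$mcmc$warmup,
                     iter = cfg$mcmc$iter, adapt = cfg$mcmc$adapt,
                     seed = stage_seed(cfg$seed, paste0("fit_", fam, s)),
                     sex = s))
        names(fits) <- cfg$families
        list(fits = fits, comparison = compare_growth(fits))
      })
      names(out) <- sexes
      out
    })
    report <- pipeline_stage(report, "contrasts", "growth", {
      if (all(c("M", "F") %in% names(report$growth))) {
        out <- lapply(cfg$families, function(fam)
          sex_difference(report$growth$F$fits[[fam]],
                         report$growth$M$fits[[fam]],
                         seed = stage_seed(cfg$seed, "contrast")))
        names(out) <- cfg$families
        out
      } else NULL
    })
  }

  if ("longevity" %in% cfg$stages) {
    report <- pipeline_stage(report, "longevity", "growth", {
      do.call(rbind, lapply(names(report$growth), function(s) {
        best <- report$growth[[s]]$comparison$family[1]
        k <- coef(report$growth[[s]]$fits[[best]])[["k"]]
        obs_max <- max(aged$age[aged$sex == s])
        cbind(longevity_table(k, obs_max, label = s), best_model = best)
      }))
    })
  }
  if ("comparative" %in% cfg$stages) {
    report <- pipeline_stage(report, "comparative", character(0),
                             comparative_stats())
  }

  report$manifest <- list(seed = cfg$seed,
                          package = "rayage",
                          version = as.character(utils::packageVersion("rayage")),
                          stages = cfg$stages,
                          n_fish = nrow(fish),
                          timestamp = NULL)
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(report, cfg)
  report
}

write_pipeline_outputs <- function(report, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  cfg_json <- out("config.json")
  cfg_list <- cfg
  cfg_list$input <- if (is.character(cfg$input)) cfg$input else NULL
  cfg_list$priors <- unclass(cfg$priors)
  cfg_list$sim <- lapply(unclass(cfg$sim), function(x)
    if (is.data.frame(x)) NULL else x)
  jsonlite::write_json(cfg_list, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- report$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_json))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(report$precision))
    jsonlite::write_json(unclass(report$precision), out("precision.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(report$age_bias))
    utils::write.csv(report$age_bias, out("age_bias.csv"), row.names = FALSE)
  if (!is.null(report$edges)) {
    utils::write.csv(as.data.frame(report$edges), out("edge_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$pairs))
    utils::write.csv(report$pairs, out("backcalc_pairs.csv"),
                     row.names = FALSE)
  if (!is.null(report$age_summary))
    utils::write.csv(report$age_summary, out("age_summary.csv"),
                     row.names = FALSE)
  if (!is.null(report$growth)) {
    summ <- do.call(rbind, lapply(names(report$growth), function(s)
      do.call(rbind, lapply(report$growth[[s]]$fits, function(f) {
        d <- f$summary; d$param <- rownames(d)
        d$family <- f$family; d$sex <- s; rownames(d) <- NULL; d
      }))))
    utils::write.csv(summ, out("posterior_summary.csv"), row.names = FALSE)
    comp <- do.call(rbind, lapply(names(report$growth), function(s)
      as.data.frame(report$growth[[s]]$comparison)))
    utils::write.csv(comp, out("model_comparison.csv"), row.names = FALSE)
  }
  if (!is.null(report$longevity))
    utils::write.csv(report$longevity, out("longevity.csv"),
                     row.names = FALSE)
  if (!is.null(report$comparative))
    jsonlite::write_json(lapply(unclass(report$comparative), as.vector),
                         out("comparative.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(cfg$out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Age-and-growth pipeline report\n")
  cat("  stages run:",
      paste(setdiff(names(x), c("errors", "manifest", "data", "truth")),
            collapse = ", "), "\n")
  if (length(x$errors) > 0) {
    cat("  stage errors:\n")
    for (nm in names(x$errors)) cat("   ", nm, ":", x$errors[[nm]], "\n")
  }
  if (!is.null(x$precision)) print(x$precision)
  if (!is.null(x$edges)) cat("  band periodicity best model:",
                             attr(x$edges, "best"), "\n")
  if (!is.null(x$growth))
    for (s in names(x$growth))
      cat(sprintf("  best growth model (%s): %s\n", s,
                  x$growth[[s]]$comparison$family[1]))
  invisible(x)
}
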