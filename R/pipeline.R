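#' Config-driven orchestration of the full analysis
#'
#' Stages run in order: data (synthesize or load) -> impute -> SARIMAX-MC
#' -> Granger -> phenology -> trends. Every stage writes its artifact as
#' plain CSV under the output directory and a JSON manifest records the
#' config echo, seeds, timings and warnings, so a rerun with the same
#' config and seed reproduces all outputs exactly.
#'
#' @name pipeline
NULL

#' Derive a stage seed from the master seed
#'
#' Documented rule: a polynomial (base-31) hash of the stage name is mixed
#' with the master seed modulo 2^31 - 1, so adding a stage never perturbs
#' the randomness of the others.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param synth a [synth_config()] (used when `panel_path` is `NULL`).
#' @param panel_path,annual_path CSVs in the [read_panel()] layout, to run
#'   on real data instead of the generator.
#' @param M imputation ensemble size.
#' @param seed master seed; stage seeds derive from it via [stage_seed()].
#' @param target response variable.
#' @param order,exog SARIMAX specification.
#' @param sarimax_method `"ml"` or `"css"`.
#' @param granger_causes candidate drivers for the causality screen.
#' @param granger_resolution `"annual"` or `"weekly"`.
#' @param windows bloom [season_windows()].
#' @param threshold_factor bloom threshold multiplier.
#' @param compare_decades two [decade_spec()]s (first vs last) for the
#'   decadal t-tests.
#' @param climatology_decades [decade_spec()] list for weekly climatologies
#'   and pairwise distribution tests.
#' @export
pipeline_config <- function(synth = synth_config(),
                            panel_path = NULL, annual_path = NULL,
                            M = 100L, seed = 1L, target = "chl",
                            order = sarimax_order(),
                            exog = default_exog_spec(),
                            sarimax_method = "ml",
                            granger_causes = c("no32", "nh4", "po4", "sio4",
                                               "temp", "salinity", "secchi",
                                               "light", "precip", "strat"),
                            granger_resolution = "annual",
                            windows = season_windows(),
                            threshold_factor = 1.05,
                            compare_decades = list(
                              decade_spec("first", 1973L, 1982L),
                              decade_spec("last", 2009L, 2019L)),
                            climatology_decades = list(
                              decade_spec("1970s", 1970L, 1979L),
                              decade_spec("1980s", 1980L, 1989L),
                              decade_spec("1990s", 1990L, 1999L),
                              decade_spec("2000s", 2000L, 2009L),
                              decade_spec("2010s", 2010L, 2019L))) {
  stopifnot(M >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list(); warns <- character(0)
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                     stage, conditionMessage(e), outdir), call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }

  # -- data --
  dat <- tick("data", {
    if (is.null(config$panel_path)) {
      cf <- config$synth
      cf$seed <- stage_seed(config$seed, "data")
      gen <- generate_panel(cf)
      panel <- apply_missingness(gen$panel, cf)
      write_panel(panel, file.path(outdir, "panel.csv"),
                  file.path(outdir, "annual.csv"))
      list(panel = panel, truth = gen$truth)
    } else {
      list(panel = read_panel(config$panel_path, config$annual_path),
           truth = NULL)
    }
  })

  # -- impute --
  imp <- tick("impute", {
    impute_panel(dat$panel, target = config$target, M = config$M,
                 seed = stage_seed(config$seed, "impute"))
  })
  g <- series_grid(dat$panel$series[[1]])
  ens_df <- cbind(g, as.data.frame(imp$ensemble$values))
  names(ens_df)[-(1:2)] <- paste0("m", seq_len(config$M))
  tick("impute_write", {
    wcsv(ens_df, "ensemble.csv")
    write_panel(imp$panel, file.path(outdir, "panel_imputed.csv"))
  })
  fully_imputed <- tapply(!imp$ensemble$mask, g$year, all)
  if (any(fully_imputed)) {
    warns <- c(warns, sprintf("fully imputed year(s): %s",
      paste(names(fully_imputed)[fully_imputed], collapse = ", ")))
  }

  # -- sarimax --
  mc <- tick("sarimax", {
    run_mc(imp$ensemble, imp$panel, order = config$order, exog = config$exog,
           method = config$sarimax_method)
  })
  tick("sarimax_write", wcsv(mc$summary, "mc_summary.csv"))

  # -- granger --
  gr <- tick("granger", {
    granger_screen(imp$panel, effect = config$target,
                   causes = config$granger_causes,
                   resolution = config$granger_resolution)
  })
  tick("granger_write", wcsv(gr, "granger.csv"))

  # -- phenology --
  ph <- tick("phenology", {
    phenology_over_ensemble(imp$ensemble, windows = config$windows,
                            factor = config$threshold_factor)
  })
  tick("phenology_write", {
    wcsv(ph$members, "phenology_members.csv")
    wcsv(ph$summary, "phenology_summary.csv")
  })

  # -- trends --
  tr <- tick("trends", {
    mean_series <- weekly_series(rowMeans(imp$ensemble$values),
                                 g$year[1], g$week[1],
                                 name = config$target)
    summ <- annual_summaries(mean_series)
    dc <- lapply(c(cumulative = "cumulative", max = "max", cv = "cv"),
                 function(f) decade_compare(summ, config$compare_decades[[1]],
                                            config$compare_decades[[2]], f))
    lt <- list(max = loglinear_trend(summ$max, summ$year),
               min = loglinear_trend(summ$min, summ$year))
    clim <- decadal_climatology(mean_series, config$climatology_decades)
    ad <- pairwise_decade_tests(mean_series, config$climatology_decades,
                                method = "asymptotic")
    list(summaries = summ, decade_tests = dc, trend_fits = lt,
         climatology = clim, ad = ad)
  })
  tick("trends_write", {
    wcsv(tr$summaries, "annual_summaries.csv")
    dt <- do.call(rbind, lapply(names(tr$decade_tests), function(f) {
      d <- tr$decade_tests[[f]]
      data.frame(field = f, t = d$t, df = d$df, p = d$p,
                 percent_change = d$percent_change)
    }))
    wcsv(dt, "decade_tests.csv")
    tf <- do.call(rbind, lapply(names(tr$trend_fits), function(f) {
      d <- tr$trend_fits[[f]]
      data.frame(field = f, slope = d$slope, intercept = d$intercept,
                 r_squared = d$r_squared, p = d$p)
    }))
    wcsv(tf, "trend_fits.csv")
    wcsv(cbind(week = 1:52, as.data.frame(tr$climatology)), "climatology.csv")
    wcsv(as.data.frame(tr$ad$p), "ad_matrix.csv")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("baybloom")),
    seed = config$seed,
    stage_seeds = list(data = stage_seed(config$seed, "data"),
                       impute = stage_seed(config$seed, "impute")),
    M = config$M,
    sarimax_order = unlist(config$order),
    sarimax_dropped = mc$n_dropped,
    timings_sec = timings,
    warnings = warns
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(data = dat, impute = imp, mc = mc, granger = gr,
                 phenology = ph, trends = tr, manifest = manifest))
}
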