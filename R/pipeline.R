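#' Read / write a per-plant trait table
#'
#' Plain CSV with standard trait abbreviations as column names; `family`
#' and `plant` identifier columns are required on read.
#'
#' @param traits data.frame
#' @param path file path
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family", "plant")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop_bad("path", paste("missing columns:", paste(miss, collapse = ", ")))
  out
}

#' Run the end-to-end trial analysis pipeline
#'
#' Orchestrates simulate -> derive -> analyze -> report over a synthetic
#' trial: generates (or reads) a trait table, derives the kite traits,
#' produces a per-trait population summary with heritabilities, fits the
#' core log-log allometries (HT~DIA, WBM~DIA by RMA), fits the canopy-form
#' archetypes on the two shape ratios, and computes the per-plant yield
#' report (predicted biomass, cannabinoid totals and yields). Writes CSV/JSON
#' outputs and a run manifest (seeds, config, file checksums, timestamps)
#' under `out_dir`.
#'
#' @param cfg a [trial_config()]
#' @param seed master seed
#' @param out_dir output directory (created if missing); `NULL` = in-memory
#'   only
#' @param stages character subset of
#'   `c("simulate", "derive", "analyze", "report")` in dependency order
#' @param k_archetypes number of canopy archetypes (default 4)
#' @return list with `traits`, `summary`, `allometry`, `archetypes`,
#'   `yield`, `manifest`
#' @export
run_pipeline <- function(cfg = trial_config(), seed = 1L, out_dir = NULL,
                         stages = c("simulate", "derive", "analyze", "report"),
                         k_archetypes = 4) {
  known <- c("simulate", "derive", "analyze", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_bad("stages", paste("unknown stage:", paste(bad, collapse = ", ")))
  stages <- known[known %in% stages]
  res <- list(manifest = list(seed = seed, started = format(Sys.time()),
                              package_version = as.character(utils::packageVersion("hempkite")),
                              stages = stages))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  if ("simulate" %in% stages) {
    sim <- t_stage("simulate", simulate_trial(cfg, seed))
    res$traits <- sim$traits
    res$truth <- sim$truth
  }
  if ("derive" %in% stages) {
    if (is.null(res$traits)) stop_bad("stages", "derive requires simulate output")
    res$traits <- t_stage("derive", {
      tr <- derive_kite_traits(res$traits)
      tr$VOL <- stem_volume(tr$DIA, tr$HT)
      tr$LI <- tr$LFN / tr$VOL
      tr$AUDPC <- vapply(seq_len(nrow(tr)), function(i)
        audpc(cfg$disease$days, c(tr$PM71[i], tr$PM86[i], tr$PM97[i])), numeric(1))
      tr$DSBM_area <- floral_biomass_per_area(tr$DSBM, tr$MCD)
      tot <- total_potential(tr$CBD_pct, tr$CBDA_pct, "CBD") +
        total_potential(tr$THC_pct, tr$THCA_pct, "THC") +
        total_potential(tr$CBC_pct, tr$CBCA_pct, "CBC") +
        total_potential(tr$CBG_pct, tr$CBGA_pct, "CBG") +
        total_potential(tr$THCV_pct, tr$THCVA_pct, "THCV") +
        total_potential(tr$CBDV_pct, tr$CBDVA_pct, "CBDV") +
        total_potential(tr$CBL_pct, tr$CBLA_pct, "CBL")
      tr$CB_total_pct <- tot
      tr$CB_yield_g <- tot / 100 * tr$DSBM * 1000
      tr
    })
  }
  if ("analyze" %in% stages) {
    if (is.null(res$traits) || !"KITE" %in% names(res$traits)) {
      stop_bad("stages", "analyze requires derive output")
    }
    tr <- res$traits
    res$summary <- t_stage("summary", {
      cols <- intersect(c("HT", "BPAIR", "INL", "MCD", "MCDH", "TRKL", "KITE",
                          "KHR", "KBA", "KC", "DIA", "VOL", "LFLTN", "LFDW",
                          "LFA", "SLA", "SPA", "PTFD", "TFD", "GLI", "PM97",
                          "AUDPC", "WBM", "DBM", "DSBM", "CB_yield_g"),
                        names(tr))
      h2_report(tr, cols)
    })
    res$allometry <- t_stage("allometry", list(
      ht_dia = fit_loglog(tr$DIA, tr$HT, "RMA"),
      wbm_dia = fit_loglog(tr$DIA, tr$WBM, "RMA"),
      lfdw_li = fit_loglog(tr$LI, tr$LFDW, "RMA"),
      spa_li = fit_loglog(tr$LI, tr$SPA, "RMA")
    ))
    res$archetypes <- t_stage("archetypes", {
      X <- as.matrix(shape_ratios(tr$HT, tr$MCD, tr$MCDH)[, c("mcd_ht", "mcdh_ht")])
      sol <- archetypal_analysis(X, k_archetypes, nrep = 5, seed = seed)
      asg <- assign_archetype(X, sol)
      list(solution = sol, labels = asg$labels)
    })
    res$segregation <- segregation_counts(flowering_class(tr$PTFD), tr$family)
  }
  if ("report" %in% stages && !is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(traits = file.path(out_dir, "traits.csv"),
               summary = file.path(out_dir, "trait_summary.csv"),
               segregation = file.path(out_dir, "segregation.csv"))
    write_trait_table(res$traits, paths["traits"])
    if (!is.null(res$summary)) utils::write.csv(res$summary, paths["summary"], row.names = FALSE)
    if (!is.null(res$segregation)) utils::write.csv(res$segregation, paths["segregation"], row.names = FALSE)
    if (!is.null(res$allometry)) {
      al <- do.call(rbind, lapply(names(res$allometry), function(nm) {
        f <- res$allometry[[nm]]
        data.frame(pair = nm, method = f$method, slope = f$slope,
                   intercept = f$intercept, r_squared = f$r_squared, n = f$n)
      }))
      paths <- c(paths, allometry = file.path(out_dir, "allometry.csv"))
      utils::write.csv(al, paths["allometry"], row.names = FALSE)
    }
    res$manifest$finished <- format(Sys.time())
    res$manifest$files <- as.list(tools::md5sum(unname(paths[file.exists(paths)])))
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
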