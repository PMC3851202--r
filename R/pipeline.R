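#' Configuration for a full pipeline run
#'
#' Either a simulation config (`sim`) or paths to real inputs
#' (`fasta`, `site_table`, optional `annotations` and
#' `homolog_table`). Analysis defaults follow the package conventions:
#' 13-residue window, amino-terminal Met discounting, alpha = 0.05,
#' Met-conservation thresholds mirroring levels >= 7, 6, 5, 4 of 8.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed (mandatory; drives simulation and makes
#'   reruns byte-identical).
#' @param sim A [synthetic_config()], or `NULL` to read real inputs.
#' @param fasta,site_table,annotations,homolog_table Input paths (used
#'   when `sim` is `NULL`).
#' @param half_width Window half-width (default 6).
#' @param discount_nterm Discount amino-terminal Met (default TRUE).
#' @param alpha Significance level (default 0.05).
#' @param conservation_threshold "High conservation" taxa count for
#'   scenario classification (default 6 of 8).
#' @param panel_thresholds Conservation levels at which enrichment is
#'   repeated (default 7, 6, 5, 4).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed, sim = NULL, fasta = NULL,
                       site_table = NULL, annotations = NULL,
                       homolog_table = NULL, half_width = 6L,
                       discount_nterm = TRUE, alpha = 0.05,
                       conservation_threshold = 6L,
                       panel_thresholds = c(7L, 6L, 5L, 4L)) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (half_width < 0L || half_width > 10L) stop("half_width must be in 0..10")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(sim) && (is.null(fasta) || is.null(site_table)))
    stop("provide either a simulation config or fasta + site_table paths")
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 fasta = fasta, site_table = site_table,
                 annotations = annotations, homolog_table = homolog_table,
                 half_width = as.integer(half_width),
                 discount_nterm = discount_nterm, alpha = alpha,
                 conservation_threshold = as.integer(conservation_threshold),
                 panel_thresholds = as.integer(panel_thresholds)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate-or-read, window statistics, conservation
#' scoring and enrichment, writing one TSV per analysis plus a
#' machine-readable JSON manifest: amino-acid composition,
#' Met-proximity with two-proportion z-tests against the
#' all-Ser/Thr/Tyr background, positional Met and VILF distributions
#' with a chi-square test of positional independence, per-site
#' hydropathy, the window-size scan, the Met-conservation heat-map
#' table with crosstalk-scenario classification, and GO enrichment for
#' the any-Met test set and per conservation threshold. Any stage
#' failure aborts the run, names the stage, and removes partial
#' outputs. Reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results and the output
#'   file paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  res <- tryCatch({
    out <- function(name) {
      p <- file.path(config$out_dir, name)
      written <<- c(written, p)
      p
    }
    log_stage <- function(...) message("[", stage, "] ", ...)

    stage <- "inputs"
    if (!is.null(config$sim)) {
      prot0 <- generate_proteome(config$sim)
      planted <- plant_phosphosites(prot0, config$sim)
      prot <- planted$proteome
      sites <- planted$sites
      fam_gen <- generate_homolog_families(prot, sites, config$sim)
      mapping <- fam_gen$mapping
      test_prot <- unique(sites$protein_id[
        sites_with_met(prot, sites, config$half_width, config$discount_nterm)])
      ann <- generate_go_annotations(prot, config$sim, test_prot)
    } else {
      prot <- read_fasta(config$fasta)
      sites <- read_site_table(config$site_table, prot)
      mapping <- if (!is.null(config$homolog_table))
        read_homolog_table(config$homolog_table) else NULL
      ann <- if (!is.null(config$annotations))
        read_go_annotations(config$annotations) else NULL
    }
    bg_sites <- enumerate_all_sty(prot)
    log_stage(length(prot$sequences), " proteins, ", nrow(sites),
              " phosphosites, ", nrow(bg_sites), " background S/T/Y sites")

    stage <- "composition"
    comp <- composition(prot, config$discount_nterm)
    write_tsv(comp, out("composition.tsv"))

    stage <- "proximity"
    all_sites <- rbind(sites, bg_sites)
    prox <- met_proximity_table(prot, all_sites, config$half_width,
                                config$discount_nterm)
    # z-test of each phospho group against the all-S/T/Y background
    ztab <- do.call(rbind, lapply(which(prox$evidence != "all_sty"), function(i) {
      j <- which(prox$residue == prox$residue[i] & prox$evidence == "all_sty")
      if (length(j) == 0L) return(NULL)
      zt <- two_proportion_z(prox$n_with_met[i], prox$n_sites[i],
                             prox$n_with_met[j], prox$n_sites[j])
      data.frame(residue = prox$residue[i], evidence = prox$evidence[i],
                 z = zt$z, p_two_sided = zt$p_two_sided)
    }))
    prox_out <- merge(as.data.frame(prox), ztab,
                      by = c("residue", "evidence"), all.x = TRUE, sort = TRUE)
    write_tsv(prox_out, out("met_proximity.tsv"))

    stage <- "positions"
    pos_parts <- lapply(c("M", "VILF"), function(cl) {
      pd_ph <- positional_distribution(prot, sites, cl, config$half_width,
                                       config$discount_nterm)
      pd_bg <- positional_distribution(prot, bg_sites, cl, config$half_width,
                                       config$discount_nterm)
      rbind(cbind(residue_class = cl, group = "phospho", as.data.frame(pd_ph)),
            cbind(residue_class = cl, group = "all_sty", as.data.frame(pd_bg)))
    })
    pos_tab <- do.call(rbind, pos_parts)
    pd_m <- pos_tab[pos_tab$residue_class == "M" & pos_tab$group == "phospho", ]
    chi_p <- if (all(pd_m$denominator > 0) && sum(pd_m$count) > 0 &&
                 any(pd_m$count < pd_m$denominator)) {
      tb <- rbind(pd_m$count, pd_m$denominator - pd_m$count)
      chi_square_independence(tb)$p_value
    } else NA_real_
    pos_tab$chisq_p_phospho_met <- chi_p
    write_tsv(pos_tab, out("positional_distribution.tsv"))

    stage <- "hydropathy"
    hyd <- hydropathy_table(prot, sites, config$half_width)
    write_tsv(hyd, out("hydropathy.tsv"))

    stage <- "scan"
    scan <- window_size_scan(prot, sites, 1:10, config$discount_nterm)
    write_tsv(scan, out("window_size_scan.tsv"))

    stage <- "conservation"
    fams <- build_families(prot, sites, mapping)
    cons <- conservation_table(fams)
    heat <- conservation_heatmap(cons)
    scen <- classify_scenarios(fams, config$conservation_threshold)
    write_tsv(cons, out("conservation_records.tsv"))
    write_tsv(heat, out("conservation_heatmap.tsv"))
    write_tsv(scen, out("crosstalk_scenarios.tsv"))
    log_stage(length(fams), " families, ", nrow(cons), " conservation records")

    stage <- "enrichment"
    enr_files <- list()
    if (!is.null(ann) && nrow(sites) > 0L) {
      sets <- define_sets(sites, prot, "any_met_in_window",
                          config$half_width, config$discount_nterm)
      enr <- run_enrichment(sets$test, sets$background, ann, config$alpha)
      write_tsv(as.data.frame(enr), out("enrichment_any_met.tsv"))
      enr_files$any_met <- enr
      for (L in config$panel_thresholds) {
        setsL <- suppressWarnings(
          define_sets(sites, prot, "conservation", config$half_width,
                      config$discount_nterm, conservation_records = cons,
                      min_level = L))
        enrL <- run_enrichment(setsL$test, setsL$background, ann, config$alpha)
        write_tsv(as.data.frame(enrL),
                  out(sprintf("enrichment_conservation_ge%d.tsv", L)))
        enr_files[[sprintf("ge%d", L)]] <- enrL
      }
    }

    stage <- "manifest"
    manifest <- list(
      package = "phosmet",
      version = as.character(utils::packageVersion("phosmet")),
      seed = config$seed,
      half_width = config$half_width,
      discount_nterm = config$discount_nterm,
      alpha = config$alpha,
      conservation_threshold = config$conservation_threshold,
      panel_thresholds = config$panel_thresholds,
      simulated = !is.null(config$sim),
      n_proteins = length(prot$sequences),
      n_sites = nrow(sites),
      n_sites_rejected = attr(sites, "n_rejected") %||% 0L,
      n_background_sty = nrow(bg_sites),
      n_families = length(fams),
      n_conservation_records = nrow(cons),
      outputs = basename(written)
    )
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(proteome = prot, sites = sites, composition = comp,
         proximity = prox_out, positions = pos_tab, hydropathy = hyd,
         scan = scan, families = fams, conservation = cons, heatmap = heat,
         scenarios = scen, enrichment = enr_files, manifest = manifest,
         files = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
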