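#' Run the regulon-analysis pipeline end to end
#'
#' Orchestrates simulate -> callpeaks -> annotate -> motif -> scan ->
#' geometry -> ffl from one configuration, with a deterministic per-stage
#' seed fan-out, and returns (and optionally writes) a run manifest whose
#' counts all trace to single module operations. Two modes are typical:
#' a full synthetic run (stage `"simulate"` enabled) and a fixture-only run
#' (simulation off, `fixtures$peak_table` pointing at a packaged or user
#' peak table).
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{stages}{Character vector of enabled stages, a subset of
#'       `c("simulate", "callpeaks", "annotate", "motif", "scan",
#'       "geometry", "ffl")`.}
#'     \item{seed}{Global integer seed; each stage derives its own seed
#'       from it and the stage name.}
#'     \item{out_dir}{Optional output directory; when given, stage outputs
#'       and `manifest.json` are written there.}
#'     \item{sim, peaks, annotation, discovery}{Optional parameter lists
#'       forwarded to [sim_config()], [peak_call_params()],
#'       [annotation_params()], [discovery_params()].}
#'     \item{scan}{Optional list: `p_threshold`.}
#'     \item{geometry}{Optional list: `threshold`.}
#'     \item{ffl}{Optional list: `theta`, `alpha`.}
#'     \item{fixtures}{Optional list of input paths used when the producing
#'       stage is disabled: `peak_table`, `genome`, `annotation`,
#'       `regulon_table`, `expression`.}
#'   }
#' @return The manifest: enabled stages, seeds, parameters, per-stage
#'   output summary, and `counts` (`n_peaks`, `n_regulon_genes`,
#'   `motif_width`, `n_with_motif`, `n_within_threshold`, `ffl_labels`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% character()
  known <- c("simulate", "callpeaks", "annotate", "motif", "scan",
             "geometry", "ffl")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(stages = stages, seed = seed, counts = list())
  st <- list()  # shared state across stages

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(stage_seed(seed, name)),
                    error = function(e) {
                      stop("stage '", name, "' failed: ", conditionMessage(e),
                           call. = FALSE)
                    })
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  run_stage("simulate", function(s) {
    cfg <- do.call(sim_config, c(list(seed = s),
                                 config$sim %||% list()))
    genome <- generate_genome(cfg)
    land <- generate_regulatory_landscape(genome, cfg)
    cov <- simulate_chip_coverage(land$genome, land$ground_truth, cfg)
    st$sim_config <<- cfg
    st$genome <<- land$genome
    st$genes <<- land$genes
    st$tus <<- land$tus
    st$ground_truth <<- land$ground_truth
    st$ip <<- cov$ip
    st$control <<- cov$control
    if (!is.null(out_dir)) {
      write_genome(st$genome, file.path(out_dir, "genome.fa"))
      write_annotation(st$genes, file.path(out_dir, "genes.tsv"))
      write_bedgraph(st$ip, file.path(out_dir, "ip.bedgraph"),
                     st$genome$name)
      write_bedgraph(st$control, file.path(out_dir, "control.bedgraph"),
                     st$genome$name)
      write_ground_truth(st$ground_truth,
                         file.path(out_dir, "ground_truth.json"))
    }
    manifest$counts$n_planted_sites <<- nrow(st$ground_truth$sites)
  })

  # load fixtures for whatever the simulation did not provide
  fx <- config$fixtures %||% list()
  if (is.null(st$genome) && !is.null(fx$genome)) {
    st$genome <- load_genome(fx$genome)
  }
  if (is.null(st$genes) && !is.null(fx$annotation)) {
    ann <- load_annotation(fx$annotation)
    st$genes <- ann$genes
    st$tus <- ann$tus
  }

  run_stage("callpeaks", function(s) {
    if (is.null(st$ip)) stop("no coverage tracks (enable 'simulate')")
    params <- do.call(peak_call_params, config$peaks %||% list())
    st$peaks <<- call_peaks(st$ip, st$control, params,
                            circular = st$genome$circular)
    if (!is.null(out_dir)) {
      write_peak_table(st$peaks, file.path(out_dir, "peaks.tsv"))
      write_bed(st$peaks, file.path(out_dir, "peaks.bed"), st$genome$name)
    }
    manifest$counts$n_peaks <<- nrow(st$peaks)
  })
  if (is.null(st$peaks) && !is.null(fx$peak_table)) {
    st$peaks <- load_peak_table(fx$peak_table)
    manifest$counts$n_peaks <- nrow(st$peaks)
  }

  run_stage("annotate", function(s) {
    if (is.null(st$peaks) || is.null(st$genes)) {
      stop("annotation needs peaks and gene models")
    }
    params <- do.call(annotation_params, config$annotation %||% list())
    st$regulon <<- build_regulon(
      st$peaks, st$genes, st$tus, params,
      genome_length = if (!is.null(st$genome)) st$genome$length,
      circular = if (!is.null(st$genome)) st$genome$circular else TRUE)
    if (!is.null(out_dir)) {
      write_regulon(st$regulon, file.path(out_dir, "regulon.tsv"))
    }
    manifest$counts$n_regulon_genes <<- nrow(st$regulon)
  })
  if (is.null(st$regulon) && !is.null(fx$regulon_table)) {
    st$regulon <- utils::read.delim(fx$regulon_table,
                                    stringsAsFactors = FALSE)
    manifest$counts$n_regulon_genes <- nrow(st$regulon)
  }

  run_stage("motif", function(s) {
    if (is.null(st$peaks) || is.null(st$genome)) {
      stop("motif discovery needs peaks and a genome")
    }
    dpar <- do.call(discovery_params,
                    c(list(rng_seed = s), config$discovery %||% list()))
    windows <- extract_summit_windows(st$peaks, st$genome, dpar$window)
    st$motif <<- discover_motif_zoops(windows, dpar)
    if (!is.null(out_dir)) {
      write_meme(st$motif, file.path(out_dir, "motif.meme"))
    }
    manifest$counts$motif_width <<- st$motif$width
    manifest$counts$motif_nsites <<- st$motif$nsites
  })

  run_stage("scan", function(s) {
    if (is.null(st$motif) || is.null(st$genome)) {
      stop("scanning needs a discovered motif and a genome")
    }
    p_thr <- (config$scan %||% list())$p_threshold %||% 1e-4
    lo <- make_log_odds(st$motif$ppm, st$motif$background, pseudocount = 0.5)
    st$sites <<- scan_genome(st$genome, lo, p_threshold = p_thr,
                             background = st$motif$background)
    st$peaks <<- assign_motifs_to_peaks(st$peaks, st$sites, st$motif$width)
    if (!is.null(out_dir)) {
      write_motif_sites(st$sites, file.path(out_dir, "motif_sites.tsv"),
                        width = st$motif$width, format = "tsv")
    }
    manifest$counts$n_scan_sites <<- nrow(st$sites)
  })

  run_stage("geometry", function(s) {
    if (is.null(st$peaks)) stop("geometry needs peaks")
    thr <- (config$geometry %||% list())$threshold %||% 50
    st$geometry <<- summit_motif_geometry(st$peaks, threshold = thr)
    manifest$counts$n_with_motif <<- st$geometry$n_with_motif
    manifest$counts$n_within_threshold <<- st$geometry$n_within_threshold
  })

  run_stage("ffl", function(s) {
    ffl_spec <- if (!is.null(st$ground_truth)) st$ground_truth$ffl_spec
    expr <- if (!is.null(fx$expression)) {
      utils::read.csv(fx$expression, stringsAsFactors = FALSE)
    } else if (!is.null(ffl_spec) && nrow(ffl_spec)) {
      simulate_expression(ffl_spec, st$sim_config, seed = s)
    } else {
      stop("ffl stage needs simulated ground truth or an expression fixture")
    }
    opts <- config$ffl %||% list()
    st$ffl <<- classify_ffl_table(expr, theta = opts$theta %||% 2,
                                  alpha = opts$alpha %||% 2)
    if (!is.null(out_dir)) {
      utils::write.table(st$ffl, file.path(out_dir, "ffl.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$counts$ffl_labels <<- stats::setNames(
      as.list(paste0(st$ffl$ffl_type,
                     ifelse(st$ffl$gate != "", paste0("-", st$ffl$gate), ""))),
      st$ffl$gene)
  })

  manifest$parameters <- config[intersect(
    names(config), c("sim", "peaks", "annotation", "discovery", "scan",
                     "geometry", "ffl"))]
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest
}

# deterministic per-stage seed: global seed plus a small stable hash of the
# stage name, kept under 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((seed + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
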