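# End-to-end orchestration: contacts -> geometry -> clustering -> substate
# statistics -> water analysis -> correlations, with deterministic CSV/JSON
# outputs. Stages are individually skippable; each stage checks that the
# upstream results it needs were computed.

.PIPELINE_STAGES <- c("contacts", "geometry", "clustering", "substates",
                      "water", "stats")

.readConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        ext <- tolower(tools::file_ext(config))
        config <- if (ext %in% c("yaml", "yml")) {
            if (!requireNamespace("yaml", quietly = TRUE))
                stop("the yaml package is needed for YAML configs",
                     call. = FALSE)
            yaml::read_yaml(config)
        } else jsonlite::read_json(config, simplifyVector = TRUE)
    }
    stopifnot(is.list(config))
    config
}

.needStage <- function(results, what, stage) {
    if (is.null(results[[what]]))
        stop("stage '", stage, "' needs the output of stage '", what,
             "', which was not run", call. = FALSE)
}

#' Run the interface-dynamics pipeline
#'
#' Executes the requested stages on a complex snapshot series and writes
#' deterministic CSV tables, a JSON summary and a plain-text log under
#' `output_dir`. Identical config and seed produce byte-identical outputs.
#'
#' The config is a list (or path to a YAML/JSON file) with entries:
#' \describe{
#'   \item{seed}{integer seed (default 1).}
#'   \item{output_dir}{output directory (created if absent).}
#'   \item{stages}{subset of contacts, geometry, clustering, substates,
#'     water, stats (default: all).}
#'   \item{input}{either `list(synthetic = list(...))` with
#'     [toyComplexSpec()] arguments plus `n_snapshots`, or
#'     `list(structure = path, trajectory = path, chains = c("A","B"))`
#'     for [loadSeries()].}
#'   \item{n_clusters}{number of substates; `NULL` uses
#'     [suggestNClusters()].}
#'   \item{contact_cutoff, interfacial_cutoff, shell_first, shell_second,
#'     region_threshold}{cutoff constants (defaults 5, 4, 3.4, 5, 25).}
#'   \item{affinity_csv}{optional per-complex table with columns
#'     `dg_bind`, `delta_asa`, `n_released` for the correlation stage.}
#' }
#'
#' @param config list or path to a YAML/JSON config file.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config) {
    cfg <- .readConfig(config)
    seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
    stages <- if (is.null(cfg$stages)) .PIPELINE_STAGES else
        match.arg(cfg$stages, .PIPELINE_STAGES, several.ok = TRUE)
    out_dir <- if (is.null(cfg$output_dir)) tempfile("ifdyn_run") else
        cfg$output_dir
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cut_contact <- cfg$contact_cutoff %||% 5.0
    cut_iface <- cfg$interfacial_cutoff %||% 4.0
    sh1 <- cfg$shell_first %||% 3.4
    sh2 <- cfg$shell_second %||% 5.0
    thr_region <- cfg$region_threshold %||% 25

    log_lines <- c("ifdyn pipeline run",
                   paste0("package_version: ",
                          as.character(utils::packageVersion("ifdyn"))),
                   paste0("seed: ", seed),
                   paste0("stages: ", paste(stages, collapse = ",")),
                   sprintf(paste0("cutoffs_A: contact=%g interfacial=%g ",
                                  "shell1=%g shell2=%g region_pct=%g"),
                           cut_contact, cut_iface, sh1, sh2, thr_region))

    # ---- input ----
    res <- list()
    if (!is.null(cfg$input$synthetic)) {
        sargs <- cfg$input$synthetic
        nsnap <- sargs$n_snapshots %||% 10
        sargs$n_snapshots <- NULL
        sargs$seed <- sargs$seed %||% seed
        spec <- do.call(toyComplexSpec, sargs)
        series <- genToySeries(spec, n_snapshots = nsnap)
        freeA <- genToySeries(spec, n_snapshots = nsnap,
                              which = "unbound_A")
        freeB <- genToySeries(spec, n_snapshots = nsnap,
                              which = "unbound_B")
    } else if (!is.null(cfg$input$structure)) {
        series <- loadSeries(cfg$input$structure, cfg$input$trajectory,
                             chains = cfg$input$chains %||% c("A", "B"))
        freeA <- freeB <- NULL
    } else stop("config$input must provide 'synthetic' or 'structure'",
                call. = FALSE)
    log_lines <- c(log_lines, paste0("n_snapshots: ", length(series)))

    # ---- contacts ----
    if ("contacts" %in% stages) {
        sets <- lapply(snapshots(series), computeContacts,
                       cutoff = cut_contact)
        res$contacts <- sets
        ctab <- do.call(rbind, lapply(sets, function(cs) {
            p <- contactPairs(cs)
            if (nrow(p) == 0L) return(NULL)
            cbind(time_ns = cs@time, p)
        }))
        writeTable(ctab %||% data.frame(time_ns = numeric(0)),
                   file.path(out_dir, "contacts.csv"))
        if (length(contactKeys(sets[[1]])) > 0)
            writeTable(conservationSeries(sets),
                       file.path(out_dir, "conservation.csv"))
        hb <- vapply(snapshots(series), countInterfaceHbonds, integer(1))
        writeTable(data.frame(
            time_ns = vapply(snapshots(series), slot, numeric(1), "time"),
            n_hbonds = hb), file.path(out_dir, "hbonds.csv"))
    }

    # ---- geometry ----
    if ("geometry" %in% stages) {
        frames <- snapshots(series)
        geo <- do.call(rbind, lapply(seq_along(frames), function(i) {
            s <- frames[[i]]
            da <- deltaAsaFromSnapshot(s)
            gd <- gapDescriptors(s, delta_asa = da)
            data.frame(time_ns = s@time, delta_asa = da,
                       gap_volume = gd$gap_volume,
                       gap_index = gd$gap_index,
                       irmsd_vs_t0 = if (i == 1) 0 else
                           interfaceRmsd(frames[[1]], s))
        }))
        res$geometry <- geo
        writeTable(geo, file.path(out_dir, "geometry.csv"))
        ctx <- asaContexts(frames[[1]])
        res$regions <- classifyRegions(ctx, threshold = thr_region)
        writeTable(res$regions, file.path(out_dir, "regions.csv"))
    }

    # ---- clustering ----
    if ("clustering" %in% stages) {
        .needStage(res, "contacts", "clustering")
        J <- jaccardMatrix(res$contacts)
        res$jaccard <- J
        sug <- suggestNClusters(J, k_max = cfg$k_max %||% 6)
        writeTable(sug$diagnostics,
                   file.path(out_dir, "cluster_diagnostics.csv"))
        k <- cfg$n_clusters %||% sug$recommended
        cl <- clusterInterfaces(J, k)
        res$clustering <- cl
        writeTable(data.frame(time_ns = cl@times, cluster = cl@labels),
                   file.path(out_dir, "cluster_labels.csv"))
        coords <- pcoaProjection(J)
        writeTable(data.frame(time_ns = cl@times, pc1 = coords[, 1],
                              pc2 = coords[, 2]),
                   file.path(out_dir, "pcoa.csv"))
        log_lines <- c(log_lines, paste0("n_clusters: ", k),
                       paste0("centroids: ",
                              paste(cl@centroids, collapse = ",")))
    }

    # ---- substate statistics ----
    if ("substates" %in% stages) {
        .needStage(res, "contacts", "substates")
        .needStage(res, "clustering", "substates")
        ft <- contactFrequencies(res$contacts, res$clustering)
        res$frequencies <- ft
        writeTable(ft[, c("contact", "cluster", "frequency")],
                   file.path(out_dir, "contact_frequencies.csv"))
        if (res$clustering@nClusters >= 2) {
            sc <- residueScores(ft)
            if (!is.null(cfg$mutation_csv)) {
                mut <- readMutationTable(cfg$mutation_csv)
                sc <- hotspotCrossref(sc, mut,
                                      threshold = cfg$hotspot_threshold
                                          %||% -2.0)
            }
            res$residue_scores <- sc
            writeTable(sc, file.path(out_dir, "residue_scores.csv"))
        } else {
            ri <- recurrenceIndex(ft)
            res$residue_scores <- ri
            writeTable(ri, file.path(out_dir, "residue_scores.csv"))
        }
    }

    # ---- water ----
    if ("water" %in% stages) {
        shells <- shellCountsSeries(series, first = sh1, second = sh2)
        res$shells <- shells
        writeTable(shells, file.path(out_dir, "shell_counts.csv"))
        iw <- do.call(rbind, lapply(snapshots(series), function(s) {
            ids <- interfacialWaters(s, cutoff = cut_iface)
            if (length(ids) == 0L) return(NULL)
            data.frame(time_ns = s@time, water_id = ids)
        }))
        writeTable(iw %||% data.frame(time_ns = numeric(0),
                                      water_id = integer(0)),
                   file.path(out_dir, "interfacial_waters.csv"))
        br <- waterMediatedContacts(series, labels = res$clustering,
                                    cutoff = cut_iface,
                                    regions = res$regions)
        res$bridges <- br
        writeTable(br, file.path(out_dir, "water_bridges.csv"))
        if (!is.null(freeA)) {
            rw <- releasedWaters(series, freeA, freeB)
            res$released <- rw
            log_lines <- c(log_lines,
                           sprintf("released_waters_first_shell: %.4f",
                                   rw$released))
        }
    }

    # ---- stats ----
    if ("stats" %in% stages && !is.null(cfg$affinity_csv)) {
        aff <- utils::read.csv(cfg$affinity_csv)
        res$affinity <- affinityCorrelations(aff)
        log_lines <- c(log_lines,
                       sprintf("cor_released_vs_affinity: %.4f",
                               res$affinity$cor_released$rho))
    }

    summary <- list(
        seed = seed, stages = stages,
        cutoffs = list(contact = cut_contact, interfacial = cut_iface,
                       shell_first = sh1, shell_second = sh2,
                       region_threshold = thr_region),
        n_snapshots = length(series),
        n_clusters = if (!is.null(res$clustering))
            res$clustering@nClusters else NULL,
        centroids = if (!is.null(res$clustering))
            res$clustering@centroids else NULL,
        released_waters = if (!is.null(res$released))
            res$released$released else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    res$output_dir <- out_dir
    invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
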