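# End-to-end pipeline: wires all stages over synthetic or file inputs and
# writes per-stage TSV/BED/Newick reports plus a JSON run manifest.

#' Pipeline configuration
#'
#' Defaults equal the study parameters: SSR thresholds 7/4/4/3/3/3, long
#' repeats >= 30 bp at Hamming distance <= 3 on the IR-reduced sequence,
#' 500-bp diversity windows with a 0.02 hotspot threshold, editing filters
#' of 10x coverage in at least 2 replicates.
#'
#' @param out_dir Output directory for stage reports.
#' @param seed Seed forwarded to the simulator.
#' @param stages Character vector of stages to run, in dependency order.
#' @param genomes Optional named list of [annotated_plastome()] objects or
#'   paths to GenBank files; `NULL` enables the `simulate` stage.
#' @param sim A [sim_config()] for the simulate stage.
#' @param min_ir_len,ssr_min_copies,repeat_min_len,repeat_max_hamming,window,step,pi_threshold,min_coverage,min_replicates
#'   Stage parameters (see the stage functions).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "partition", "repeats",
                                       "diversity", "structure", "editing",
                                       "expression"),
                            genomes = NULL, sim = sim_config(seed = seed),
                            min_ir_len = 1000L,
                            ssr_min_copies = c(7L, 4L, 4L, 3L, 3L, 3L),
                            repeat_min_len = 30L, repeat_max_hamming = 3L,
                            window = 500L, step = 500L, pi_threshold = 0.02,
                            min_coverage = 10L, min_replicates = 2L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 genomes = genomes, sim = sim, min_ir_len = min_ir_len,
                 ssr_min_copies = ssr_min_copies,
                 repeat_min_len = repeat_min_len,
                 repeat_max_hamming = repeat_max_hamming,
                 window = window, step = step, pi_threshold = pi_threshold,
                 min_coverage = min_coverage,
                 min_replicates = min_replicates),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; a failing stage stops its dependents but
#' independent stages still complete. A `manifest.json` in the output
#' directory records the package version, parameters, stage status and
#' output checksums, so a rerun with the identical manifest reproduces
#' identical outputs for the deterministic stages.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  res <- list()
  run_stage <- function(name, deps, expr) {
    if (!name %in% cfg$stages) {
      status[[name]] <<- "disabled"
      return(invisible(NULL))
    }
    failed_dep <- deps[vapply(deps, function(d)
      !identical(status[[d]], "ok") && d %in% cfg$stages, TRUE)]
    if (length(failed_dep)) {
      status[[name]] <<- paste0("skipped (dependency failed: ",
                                paste(failed_dep, collapse = ","), ")")
      return(invisible(NULL))
    }
    status[[name]] <<- tryCatch({
      res[[name]] <<- force(expr)
      "ok"
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    invisible(NULL)
  }

  run_stage("simulate", character(0), {
    sim <- simulate_plastome_set(cfg$sim)
    for (h in names(sim$plastomes))
      write_plastome(sim$plastomes[[h]],
                     file.path(cfg$out_dir, paste0(h, ".fasta")),
                     file.path(cfg$out_dir, paste0(h, ".gff3")))
    aln_ss <- Biostrings::DNAStringSet(sim$alignment$rows)
    names(aln_ss) <- sim$alignment$names
    Biostrings::writeXStringSet(aln_ss,
                                file.path(cfg$out_dir, "alignment.fasta"))
    sim
  })

  plastomes <- if (!is.null(cfg$genomes)) {
    lapply(cfg$genomes, function(g)
      if (inherits(g, "annotated_plastome")) g else read_plastome(g))
  } else res$simulate$plastomes
  alignment <- res$simulate$alignment

  run_stage("partition", "simulate", {
    parts <- lapply(plastomes, detect_quadripartite, cfg$min_ir_len)
    reports <- do.call(rbind, lapply(names(parts), function(h)
      cbind(genome = h, region_report(plastomes[[h]], parts[[h]]))))
    census <- do.call(rbind, lapply(names(parts), function(h)
      cbind(genome = h, gene_census(plastomes[[h]]))))
    write_tsv(reports, file.path(cfg$out_dir, "region_report.tsv"))
    write_tsv(census, file.path(cfg$out_dir, "gene_census.tsv"))
    list(partitions = parts, report = reports, census = census)
  })

  run_stage("repeats", "partition", {
    out <- lapply(names(plastomes), function(h) {
      red <- ir_reduced_seq(plastomes[[h]], res$partition$partitions[[h]])
      ssrs <- find_ssrs(red, cfg$ssr_min_copies,
                        features = plastomes[[h]]$features)
      reps <- find_long_repeats(red, cfg$repeat_min_len,
                                cfg$repeat_max_hamming)
      write_tsv(ssrs, file.path(cfg$out_dir, paste0("ssrs_", h, ".tsv")))
      write_tsv(reps, file.path(cfg$out_dir, paste0("repeats_", h, ".tsv")))
      list(ssrs = ssrs, repeats = reps)
    })
    names(out) <- names(plastomes)
    census <- do.call(rbind, lapply(names(out), function(h) {
      tab <- tabulate(out[[h]]$ssrs$unit_len, 6L)
      data.frame(genome = h, unit_len = 1:6, n = tab)
    }))
    write_tsv(census, file.path(cfg$out_dir, "ssr_census.tsv"))
    c(out, list(ssr_census = census))
  })

  run_stage("diversity", "simulate", {
    track <- sliding_window_pi(alignment, cfg$window, cfg$step)
    hots <- call_hotspots(track, cfg$pi_threshold)
    write_tsv(track, file.path(cfg$out_dir, "pi_windows.tsv"))
    write_tsv(hots, file.path(cfg$out_dir, "pi_hotspots.tsv"))
    # BED: 0-based half-open reference coordinates
    if (nrow(hots))
      writeLines(sprintf("%s\t%d\t%d\tpi=%.4f", alignment$reference,
                         hots$ref_start - 1L, hots$ref_end, hots$pi),
                 file.path(cfg$out_dir, "pi_hotspots.bed"))
    idt <- lapply(setdiff(alignment$names, alignment$reference),
                  function(o) identity_track(alignment, o,
                                             window = cfg$window,
                                             step = cfg$step))
    names(idt) <- setdiff(alignment$names, alignment$reference)
    for (o in names(idt))
      write_tsv(idt[[o]], file.path(cfg$out_dir,
                                    paste0("identity_", o, ".tsv")))
    list(track = track, hotspots = hots, identity = idt)
  })

  run_stage("structure", "partition", {
    ref <- names(plastomes)[1L]
    invs <- do.call(rbind, lapply(setdiff(names(plastomes), ref), function(h) {
      d <- detect_inversions(gene_order(plastomes[[ref]]),
                             gene_order(plastomes[[h]]))
      if (nrow(d) == 0L) return(NULL)
      cbind(genomes = paste(ref, h, sep = "/"), d)
    }))
    if (is.null(invs))
      invs <- data.frame(genomes = character(), kind = character(),
                         genes = character(), a_start = integer(),
                         a_end = integer(), b_start = integer(),
                         b_end = integer())
    pam <- presence_absence_matrix(plastomes)
    bounds <- do.call(rbind, lapply(names(plastomes), function(h)
      cbind(genome = h,
            ssc_boundary_report(plastomes[[h]],
                                res$partition$partitions[[h]]))))
    write_tsv(invs, file.path(cfg$out_dir, "structural_differences.tsv"))
    write_tsv(cbind(genome = rownames(pam), as.data.frame(pam)),
              file.path(cfg$out_dir, "ndh_presence_absence.tsv"))
    write_tsv(bounds, file.path(cfg$out_dir, "junction_genes.tsv"))
    list(inversions = invs, presence_absence = pam, boundaries = bounds)
  })

  run_stage("editing", "simulate", {
    out <- lapply(names(plastomes), function(h) {
      sim_p <- simulate_pileups(cfg$sim, plastomes[[h]])
      sites <- call_editing_sites(sim_p$pileups, plastomes[[h]],
                                  editing_filter_config(cfg$min_coverage,
                                                        cfg$min_replicates))
      write_tsv(sites, file.path(cfg$out_dir,
                                 paste0("editing_sites_", h, ".tsv")))
      list(pileups = sim_p, sites = sites,
           spectrum = transition_spectrum(sites))
    })
    names(out) <- names(plastomes)
    out
  })

  run_stage("expression", character(0), {
    sc <- simulate_counts(cfg$sim)
    norm <- rle_normalize(sc$counts)
    lt <- log_transform(norm$normalized)
    cl <- cluster_profiles(lt)
    write_tsv(cbind(gene = rownames(norm$normalized),
                    as.data.frame(round(norm$normalized, 3))),
              file.path(cfg$out_dir, "counts_normalized.tsv"))
    write_tsv(data.frame(sample = names(norm$size_factors),
                         size_factor = round(norm$size_factors, 4)),
              file.path(cfg$out_dir, "size_factors.tsv"))
    write_tsv(cbind(gene = rownames(lt),
                    as.data.frame(round(lt[, cl$order], 3))),
              file.path(cfg$out_dir, "log_counts_leaf_ordered.tsv"))
    writeLines(cl$newick, file.path(cfg$out_dir, "expression_dendrogram.nwk"))
    list(counts = sc, normalized = norm, clustering = cl)
  })

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "plastomics",
    version = as.character(utils::packageVersion("plastomics")),
    seed = cfg$seed,
    parameters = cfg[c("min_ir_len", "ssr_min_copies", "repeat_min_len",
                       "repeat_max_hamming", "window", "step",
                       "pi_threshold", "min_coverage", "min_replicates")],
    stages = status,
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = res, status = status, manifest = manifest))
}
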