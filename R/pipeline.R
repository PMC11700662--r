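#' Run the full pipeline from a configuration
#'
#' Orchestrates ingest (files or synthetic generation), preprocessing,
#' per-cell network construction, GIM assembly, marker and dark-gene
#' detection, representative-network aggregation, structural entropy, and
#' GEM-vs-GIM evaluation. All stage outputs are written into one run
#' directory with fixed child names, and a JSON manifest records the
#' complete effective configuration, input digests, per-stage timings and
#' output paths. Re-running with the same configuration and inputs
#' reproduces identical outputs.
#'
#' The configuration is a YAML file (or an equivalent named list) with the
#' blocks:
#' \preformatted{
#' out_dir: runs/demo
#' seed: 7
#' input:                      # either this block ...
#'   matrix: counts.csv
#'   format: csv               # csv | tsv | mtx
#'   meta: meta.csv
#'   orientation: genes-by-cells
#'   gene_labels: genes.txt    # mtx only
#'   cell_labels: cells.txt    # mtx only
#' synthetic:                  # ... or this one
#'   regime: increase          # increase | flat | decrease | dark
#'   n_genes: 200
#'   n_cells_per_group: 150
#' params:                     # any pipeline_config() field
#'   alpha: 0.01
#'   damping: 0.85
#' }
#'
#' @param config Path to a YAML configuration file, or a named list with
#'   the same structure.
#' @return The run manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  params <- do.call(pipeline_config,
                    c(config$params,
                      if (!is.null(config$seed) &&
                          is.null(config$params$seed))
                        list(seed = config$seed)))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "cense",
                   version = as.character(packageVersion("cense")),
                   seed = params$seed, config = config,
                   effective_params = unclass(params),
                   stages = list(), outputs = list())
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  register <- function(name, path) {
    manifest$outputs[[name]] <<- path
  }

  gem <- stage("ingest", function() {
    if (!is.null(config$input)) {
      inp <- config$input
      manifest$input_digests <<- lapply(
        Filter(Negate(is.null),
               list(matrix = inp$matrix, meta = inp$meta,
                    gene_labels = inp$gene_labels,
                    cell_labels = inp$cell_labels)),
        function(f) unname(tools::md5sum(f)))
      read_expression(inp$matrix, inp$format, inp$meta,
                      orientation = inp$orientation %||% "genes-by-cells",
                      gene_path = inp$gene_labels,
                      cell_path = inp$cell_labels)
    } else if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      truth <- if (identical(syn$regime, "dark"))
        dark_gene_truth(n_genes = syn$n_genes %||% 200L,
                        seed = params$seed)
      else regime_presets(syn$regime %||% "flat",
                          n_genes = syn$n_genes %||% 200L,
                          seed = params$seed)
      sim <- generate_gem(truth$n_genes,
                          syn$n_cells_per_group %||% 150L, truth)
      write_truth(truth, file.path(out, "truth.json"))
      register("truth", file.path(out, "truth.json"))
      sim$gem
    } else stop("config needs an 'input' or a 'synthetic' block")
  })

  gem <- stage("preprocess", function()
    preprocess_gem(gem, params$scale_target, params$log_base))
  write_expression(gem, file.path(out, "gem.tsv"), "tsv",
                   meta_path = file.path(out, "cell_meta.tsv"))
  register("gem", file.path(out, "gem.tsv"))
  register("cell_meta", file.path(out, "cell_meta.tsv"))

  nets <- stage("networks", function() build_all_networks(gem, params))
  write_networks(nets, file.path(out, "networks.tsv"))
  register("networks", file.path(out, "networks.tsv"))

  gim <- stage("gim", function() build_gim(gem, nets, params))
  write_gim(gim, file.path(out, "gim.tsv"))
  register("gim", file.path(out, "gim.tsv"))

  labels <- gem$cell_meta$age_group
  mk <- stage("markers", function() {
    gem_mk <- t_test_markers(gem$values, labels, k = params$top_k,
                             matrix_kind = "GEM")
    gim_mk <- t_test_markers(gim$values, labels, k = params$top_k,
                             matrix_kind = "GIM")
    dark <- dark_genes(gim_mk, gem_mk, params$alpha_net,
                       params$alpha_expr)
    list(gem = gem_mk, gim = gim_mk, dark = dark)
  })
  write.table(mk$gem, file.path(out, "markers_gem.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(mk$gim, file.path(out, "markers_gim.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(mk$dark, file.path(out, "dark_genes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  register("markers_gem", file.path(out, "markers_gem.tsv"))
  register("markers_gim", file.path(out, "markers_gim.tsv"))
  register("dark_genes", file.path(out, "dark_genes.tsv"))

  stage("aggregate", function() {
    for (grp in c("young", "old", "combined")) {
      cells <- if (grp == "combined") gem$cell_ids else
        gem$cell_ids[labels == grp]
      if (!length(cells)) next
      rep <- representative_network(nets, cells, age_group = grp)
      write_type_network(rep, file.path(out, paste0("network_", grp,
                                                    ".tsv")))
      register(paste0("network_", grp),
               file.path(out, paste0("network_", grp, ".tsv")))
    }
    mix <- mixed_marker_network(
      representative_network(nets, gem$cell_ids[labels == "young"],
                             age_group = "young"),
      representative_network(nets, gem$cell_ids[labels == "old"],
                             age_group = "old"),
      attr(mk$gim, "top_up_in_young"), attr(mk$gim, "top_up_in_old"))
    write_type_network(mix$young, file.path(out, "mixed_markers_young.tsv"))
    write_type_network(mix$old, file.path(out, "mixed_markers_old.tsv"))
    register("mixed_markers_young",
             file.path(out, "mixed_markers_young.tsv"))
    register("mixed_markers_old", file.path(out, "mixed_markers_old.tsv"))
    invisible(NULL)
  })

  stage("entropy", function() {
    ks <- c(10L, 50L, 100L)
    ks <- ks[ks <= length(gem$gene_ids)]
    sets <- lapply(ks, function(kk) top_markers(mk$gim, "both", kk))
    names(sets) <- paste0("markers", ks)
    et <- per_cell_entropy(nets, gem$cell_meta, sets, params$log_base)
    write_entropy(et, file.path(out, "entropy.tsv"),
                  file.path(out, "entropy_summary.tsv"))
    register("entropy", file.path(out, "entropy.tsv"))
    register("entropy_summary", file.path(out, "entropy_summary.tsv"))
    cmp <- lapply(unique(gem$cell_meta$cell_type), function(ct) {
      sub <- gem$cell_meta[gem$cell_meta$cell_type == ct, ]
      if (min(table(factor(sub$age_group,
                           c("young", "old")))) < 2) return(NULL)
      as.data.frame(compare_groups(et, ct))
    })
    cmp <- do.call(rbind, cmp)
    if (!is.null(cmp)) {
      write.table(cmp, file.path(out, "entropy_comparison.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      register("entropy_comparison",
               file.path(out, "entropy_comparison.tsv"))
    }
    invisible(NULL)
  })

  stage("evaluate", function() {
    n_pcs <- min(6L, dim(gem)[1] - 1L, dim(gem)[2] - 1L)
    scan <- pc_pair_scan(pca_embed(gem$values, n_pcs),
                         pca_embed(gim$values, n_pcs), labels,
                         max_pc = n_pcs, seed = params$seed)
    write.table(scan, file.path(out, "evaluation.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    register("evaluation", file.path(out, "evaluation.tsv"))
    invisible(NULL)
  })

  missing <- !vapply(manifest$outputs, file.exists, TRUE)
  if (any(missing))
    stop("manifest lists missing outputs: ",
         paste(names(manifest$outputs)[missing], collapse = ", "))
  write_manifest()
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
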