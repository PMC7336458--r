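#' Full guided-assembly workflow
#'
#' Runs the complete workflow: unguided pre-coloring assembly of the reads,
#' in silico digestion of the pre-coloring contigs, placement of the contig
#' maps on the genome-wide reference optical map, transfer of the globally
#' unique reference fragment colors to the contigs, read-to-contig mapping
#' and read coloring (with optional tail extension and color-gap
#' adjustment), and finally the color-guided post-coloring assembly in which
#' inconsistent overlap-graph edges are removed.
#'
#' @param reads Named character vector, `DNAStringSet`, or FASTA path.
#' @param ref_maps Stacked map tibble of the genome-wide optical map (one
#'   map per chromosome).
#' @param enzyme A [restriction_enzyme()] used to digest the contigs.
#' @param scoring An [om_scoring_params()].
#' @param coloring A [coloring_options()].
#' @param guidance A [guidance_params()].
#' @param overlaps Optional precomputed read-overlap PAF tibble.
#' @param quiet Suppress per-stage progress messages.
#' @return An `om_pipeline` object: list with `pre` and `post` assemblies,
#'   `contig_maps`, `placements`, `colored_contigs`, `read_paf`,
#'   `colored_reads`, `color_map`, `ref_coloring`.
#' @export
run_pipeline <- function(reads, ref_maps, enzyme = xhoi(),
                         scoring = om_scoring_params(),
                         coloring = coloring_options(),
                         guidance = guidance_params(),
                         overlaps = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  seqs <- as_dna(reads)
  say("reads: %d (%.2f Mbp)", length(seqs),
      sum(Biostrings::width(seqs)) / 1e6)
  if (is.null(overlaps)) overlaps <- overlap_reads(seqs)
  say("read overlaps: %d dovetail record(s)", nrow(overlaps))
  pre <- assemble(seqs, overlaps, colors = NULL, params = guidance)
  say("pre-coloring contigs: %d", nrow(pre$unitigs))
  contig_seqs <- setNames(pre$unitigs$sequence, pre$unitigs$unitig_id)
  contig_maps <- digest_genome(contig_seqs, enzyme)
  refc <- assign_reference_colors(ref_maps)
  scoring$min_s_score <- coloring$min_s_score
  placements <- place_contigs(contig_maps, ref_maps, scoring)
  say("contigs placed on the reference map: %d / %d", length(placements),
      length(contig_seqs))
  colored_contigs <- color_contigs(contig_maps, placements, refc)
  read_paf <- map_reads(seqs, contig_seqs)
  colored <- color_reads(read_paf, colored_contigs, coloring)
  say("reads colored: %d (uncolored: %d)", nrow(colored),
      length(seqs) - nrow(colored))
  color_map <- NULL
  if (coloring$adjust_colors && nrow(colored) > 0L) {
    adj <- adjust_colors(colored, refc)
    colored <- adj$reads
    color_map <- adj$color_map
  }
  post <- assemble(seqs, overlaps, colors = colored, params = guidance)
  say("inconsistent edges removed: %d", post$n_edges_removed)
  say("post-coloring contigs: %d", nrow(post$unitigs))
  structure(
    list(pre = pre, post = post, contig_maps = contig_maps,
         placements = placements, colored_contigs = colored_contigs,
         read_paf = read_paf, colored_reads = colored,
         color_map = color_map, ref_coloring = refc),
    class = "om_pipeline"
  )
}

#' @export
print.om_pipeline <- function(x, ...) {
  cat("<om_pipeline>\n  pre : ")
  print(x$pre)
  cat("  post: ")
  print(x$post)
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x An `om_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts and contiguity statistics.
#' @export
glance.om_pipeline <- function(x, ...) {
  tibble(
    n_pre_unitigs = nrow(x$pre$unitigs),
    n_post_unitigs = nrow(x$post$unitigs),
    n_contigs_placed = length(x$placements),
    n_reads_colored = nrow(x$colored_reads),
    n_edges_removed = x$post$n_edges_removed,
    pre_n50 = glance(x$pre)$n50,
    post_n50 = glance(x$post)$n50
  )
}

#' Pipeline configuration from YAML
#'
#' Reads a YAML configuration (see `inst/extdata/default_config.yaml` for
#' the schema with full defaults) and returns the typed parameter objects.
#' Values missing from `path` fall back to the defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return List with `enzyme`, `scoring`, `coloring`, `guidance`,
#'   `simulation`, and `seed`.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(
    system.file("extdata", "default_config.yaml", package = "omguide")
  )
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (section in names(user)) {
      if (is.list(user[[section]])) {
        cfg[[section]] <- utils::modifyList(cfg[[section]] %||% list(),
                                            user[[section]])
      } else {
        cfg[[section]] <- user[[section]]
      }
    }
  }
  list(
    enzyme = restriction_enzyme(cfg$enzyme$name, cfg$enzyme$motif,
                                cfg$enzyme$cut_offset),
    scoring = do.call(om_scoring_params, cfg$scoring),
    coloring = do.call(coloring_options, cfg$coloring),
    guidance = do.call(guidance_params, cfg$guidance),
    simulation = do.call(simulation_config,
                         c(list(seed = cfg$seed), cfg$simulation)),
    seed = cfg$seed
  )
}
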