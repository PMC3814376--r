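# End-to-end orchestration: GRO classification and ESR subtraction, gene-class
# enrichments, promoter geometry and TFBS matrices, composition and
# conservation profiles, nucleosome organisation and dynamics, remodeler and
# histone-mark enrichment, and curvature-symmetry profiles, bundled into one
# deterministic report.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

class_fisher <- function(subset, class_set, universe) {
  subset <- intersect(subset, universe)
  class_set <- intersect(class_set, universe)
  a <- length(intersect(subset, class_set))
  b <- length(subset) - a
  cc <- length(class_set) - a
  d <- length(universe) - a - b - cc
  fisher_exact_2x2(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE))
}

#' Run the full analysis pipeline on a world
#'
#' Executes every stage on a synthetic (or equivalently structured) world:
#' differential transcription from the GRO table, ESR subtraction, functional
#' gene-class enrichment, promoter size and bidirectionality, TFBS bin
#' matrices, GC / PR2-skew / conservation meta-profiles, nucleosome spacing
#' and occupancy, dynamic-nucleosome overlap, remodeler-target and
#' histone-mark enrichment, and curvature-symmetry profiles. Fully
#' deterministic given `seed`. When `out_dir` is given, one TSV per analysis
#' plus a JSON summary are written; on any stage failure nothing is left
#' behind.
#'
#' @param world A `synthetic_world` (from [generate_world()] or
#'   [read_world()]).
#' @param out_dir Optional output directory for TSVs and `summary.json`.
#' @param up_threshold,down_threshold Fold-change cut-offs (1.5 / 0.65).
#' @param max_span Bidirectional-promoter TSS span limit (600 bp).
#' @param alpha Significance flag threshold (0.001).
#' @param n_trials Bootstrap trials (default 1000).
#' @param seed Integer seed governing every stochastic step (default 1).
#' @param profile_range Half-extent of TSS profiles in bp (default 500).
#' @return A `chromarch_report` list; see components in the examples.
#' @export
run_pipeline <- function(world, out_dir = NULL,
                         up_threshold = 1.5, down_threshold = 0.65,
                         max_span = 600L, alpha = 0.001,
                         n_trials = 1000L, seed = 1L,
                         profile_range = 500L) {
  if (!inherits(world, "synthetic_world")) {
    abort("`world` must be a synthetic_world (generate_world() or read_world()).")
  }
  for (part in c("genes", "gro", "nucleosomes", "marks")) {
    if (is.null(world[[part]])) {
      abort(sprintf("Pipeline stage 'input' failed: world is missing '%s'.", part))
    }
  }
  genes <- check_genes(world$genes)
  up <- profile_range; dn <- profile_range

  changes <- stage("gro", transcription_changes(
    world$gro, up_threshold = up_threshold, down_threshold = down_threshold))
  concordance <- stage("gro", replicate_concordance(world$gro))
  sets <- stage("sets", subtract_esr(
    changes,
    esr_up = world$gene_lists$esr_up %||% character(),
    esr_down = world$gene_lists$esr_down %||% character()))
  universe <- sets$universe
  set_list <- list(up = sets$up_strict, down = sets$down_strict)
  gene_sets <- list(
    all = genes,
    up = genes[genes$gene_id %in% sets$up_strict, ],
    down = genes[genes$gene_id %in% sets$down_strict, ]
  )

  classes <- stage("classes", {
    purrr::map_dfr(c("essential", "tata"), function(cl) {
      members <- world$gene_lists[[cl]] %||% character()
      purrr::imap_dfr(set_list, function(ids, set_name) {
        enr <- relative_enrichment(intersect(ids, universe), members, universe)
        tibble(class = cl, set = set_name, observed = enr$observed,
               expected = enr$expected, ratio = enr$ratio,
               p_value = class_fisher(ids, members, universe),
               method = "fisher")
      })
    })
  })

  promoters <- stage("promoter", promoter_regions(
    genes, chrom_lengths = world$chrom_lengths, max_span = max_span))
  promoter_summary <- stage("promoter", {
    purrr::imap_dfr(
      list(all = genes$gene_id, up = sets$up_strict, down = sets$down_strict),
      function(ids, set_name) {
        p <- promoters[promoters$gene_id %in% ids, ]
        tibble(set = set_name, n = nrow(p),
               mean_promoter_length = mean(p$length),
               frac_bidirectional = mean(p$kind == "bidirectional"))
      })
  })

  tfbs_matrices <- stage("tfbs", {
    lapply(gene_sets, function(g) {
      if (nrow(g) == 0) return(NULL)
      tfbs_bin_matrix(world$tfbs, g, normalize = "raw")
    })
  })

  composition <- stage("composition", {
    stats_wanted <- c("gc_fraction", "at_skew", "gc_skew")
    out <- list()
    for (st in stats_wanted) {
      for (sn in names(gene_sets)) {
        if (nrow(gene_sets[[sn]]) == 0) next
        out[[paste(st, sn, sep = ".")]] <- composition_meta_profile(
          world$genome, gene_sets[[sn]], statistic = st,
          upstream = up, downstream = dn)
      }
    }
    out
  })

  conservation <- stage("conservation", {
    if (is.null(world$tracks$conservation)) NULL else {
      lapply(gene_sets[vapply(gene_sets, nrow, 0L) > 0], function(g) {
        conservation_meta_profile(world$tracks$conservation, g,
                                  upstream = up, downstream = dn)
      })
    }
  })

  spacing <- stage("spacing", {
    sp <- gene_nucleosome_spacing(genes, world$nucleosomes)
    sp <- left_join(sp, select(tibble::as_tibble(genes), "gene_id"), by = "gene_id")
    per_set <- purrr::imap_dfr(
      list(all = genes$gene_id, up = sets$up_strict, down = sets$down_strict),
      function(ids, set_name) {
        s <- sp[sp$gene_id %in% ids & sp$defined, ]
        tibble(set = set_name, n_genes = nrow(s),
               mean_spacing = mean(s$mean_spacing))
      })
    list(per_gene = sp, per_set = per_set)
  })

  occupancy <- stage("occupancy", {
    lapply(gene_sets[vapply(gene_sets, nrow, 0L) > 0], function(g) {
      occupancy_meta_profile(world$nucleosomes, g, world$chrom_lengths,
                             upstream = up, downstream = dn)
    })
  })

  dynamics <- stage("dynamics", {
    labels_present <- intersect(unique(world$nucleosomes$label),
                                c("appearing", "evicted", "fragile"))
    out <- list()
    for (lb in labels_present) {
      for (sn in names(gene_sets)) {
        if (nrow(gene_sets[[sn]]) == 0) next
        out[[paste(lb, sn, sep = ".")]] <- dynamic_overlap_profile(
          world$nucleosomes, gene_sets[[sn]], world$chrom_lengths, label = lb,
          upstream = up, downstream = dn)
      }
    }
    out
  })

  remodelers <- stage("remodelers", {
    targets <- world$gene_lists[grepl("^remodeler_", names(world$gene_lists))]
    names(targets) <- sub("^remodeler_", "", names(targets))
    if (length(targets) == 0) NULL else {
      remodeler_enrichment(set_list, targets, universe,
                           n_trials = n_trials, seed = seed)
    }
  })

  marks <- stage("marks", {
    purrr::imap_dfr(set_list, function(ids, set_name) {
      if (length(intersect(ids, universe)) == 0) return(tibble())
      mutate(histone_mark_enrichment(world$marks, ids, universe, alpha = alpha),
             set = set_name)
    })
  })

  symcurv <- stage("symcurv", {
    lapply(gene_sets[vapply(gene_sets, nrow, 0L) > 0], function(g) {
      symcurv_meta_profile(world$genome, g, upstream = up, downstream = dn)
    })
  })

  report <- structure(
    list(parameters = list(up_threshold = up_threshold,
                           down_threshold = down_threshold,
                           max_span = max_span, alpha = alpha,
                           n_trials = n_trials, seed = seed,
                           profile_range = profile_range),
         changes = changes, concordance = concordance, sets = sets,
         classes = classes, promoters = promoters,
         promoter_summary = promoter_summary,
         tfbs_matrices = tfbs_matrices, composition = composition,
         conservation = conservation, spacing = spacing,
         occupancy = occupancy, dynamics = dynamics,
         remodelers = remodelers, marks = marks, symcurv = symcurv),
    class = "chromarch_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.chromarch_report <- function(x, ...) {
  cat("chromarch pipeline report\n")
  print(x$sets)
  cat(sprintf("  stages: %s\n",
              paste(setdiff(names(x), "parameters"), collapse = ", ")))
  invisible(x)
}

profile_to_list <- function(p) {
  list(offset = p$offset, value = p$value, n_genes = attr(p, "n_genes"),
       statistic = attr(p, "statistic"),
       normalization = attr(p, "normalization"))
}

#' Write a pipeline report to disk
#'
#' Emits one TSV per tabular analysis and a `summary.json` holding set
#' sizes, enrichment tables and profile arrays. Partial output is removed if
#' writing fails midway.
#'
#' @param report A `chromarch_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) abort(sprintf("Cannot create directory '%s'.", out_dir))
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    abort(sprintf("Pipeline stage 'write' failed: %s", conditionMessage(e)))
  }
  tryCatch({
    wr <- function(df, name) {
      f <- file.path(out_dir, name)
      readr::write_tsv(as_tibble(df), f, progress = FALSE)
      written <<- c(written, f)
    }
    wr(report$changes, "transcription_changes.tsv")
    wr(report$concordance, "replicate_concordance.tsv")
    wr(report$classes, "class_enrichment.tsv")
    wr(report$promoters, "promoters.tsv")
    wr(report$promoter_summary, "promoter_summary.tsv")
    wr(report$spacing$per_gene, "nucleosome_spacing.tsv")
    wr(report$spacing$per_set, "nucleosome_spacing_summary.tsv")
    if (!is.null(report$remodelers)) wr(report$remodelers, "remodeler_enrichment.tsv")
    wr(report$marks, "histone_mark_enrichment.tsv")

    summary <- list(
      parameters = report$parameters,
      set_sizes = list(
        up_raw = length(report$sets$up_raw),
        down_raw = length(report$sets$down_raw),
        up_strict = length(report$sets$up_strict),
        down_strict = length(report$sets$down_strict),
        universe = length(report$sets$universe)),
      esr_overlap = as.list(report$sets$esr_overlap),
      class_enrichment = report$classes,
      promoter_summary = report$promoter_summary,
      spacing = report$spacing$per_set,
      remodelers = report$remodelers,
      marks = report$marks,
      profiles = c(
        lapply(report$composition, profile_to_list),
        lapply(report$conservation %||% list(), profile_to_list),
        lapply(report$occupancy, profile_to_list),
        lapply(report$dynamics, profile_to_list),
        lapply(report$symcurv, profile_to_list))
    )
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    written <<- c(written, f)
  }, error = on_fail)
  invisible(written)
}
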