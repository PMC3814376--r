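# Plain-text serialisation of a synthetic world and the matching readers.
# Interval files are BED-style 0-based half-open; FASTA for the genome;
# bedGraph for score tracks; TSV for GRO and mark tables; one id per line
# for gene lists; YAML for the configuration.

write_bed <- function(df, path, cols) {
  readr::write_tsv(df[, cols], path, col_names = FALSE, progress = FALSE)
}

#' Write a synthetic world to a directory
#'
#' Emits `genome.fa`, `genes.bed` (BED6, name = gene id, score column holds
#' 0, strand), `nucleosomes.bed` (BED4, name = label), `tfbs.bed` (BED6,
#' name = factor), one bedGraph per score track, `gro.tsv`, `marks.tsv`,
#' `gene_lists/<name>.txt`, `truth.tsv` and `config.yaml`. Everything
#' round-trips through [read_world()].
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  if (!inherits(world, "synthetic_world")) abort("`world` must be a synthetic_world.")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) abort(sprintf("Cannot create directory '%s'.", dir))
  written <- character()
  emit <- function(f) written <<- c(written, f)

  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(world$genome), fa)
  emit(fa)

  genes_bed <- world$genes %>%
    mutate(score = 0L) %>%
    select("chrom", "start", "end", "gene_id", "score", "strand")
  write_bed(genes_bed, f <- file.path(dir, "genes.bed"),
            names(genes_bed)); emit(f)

  write_bed(world$nucleosomes, f <- file.path(dir, "nucleosomes.bed"),
            c("chrom", "start", "end", "label")); emit(f)

  tf <- world$tfbs
  if (nrow(tf) == 0) {
    tf <- tibble(chrom = character(), start = integer(), end = integer(),
                 factor = character(), score = integer(), strand = character())
  } else {
    tf <- tf %>% mutate(score = 0L) %>%
      select("chrom", "start", "end", "factor", "score", "strand")
  }
  write_bed(tf, f <- file.path(dir, "tfbs.bed"), names(tf)); emit(f)

  for (tn in names(world$tracks)) {
    f <- file.path(dir, paste0(tn, ".bedGraph"))
    bg <- purrr::imap_dfr(world$tracks[[tn]], function(v, ch) {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      tibble(chrom = ch, start = c(0L, head(ends, -1)), end = ends,
             value = r$values)
    })
    readr::write_tsv(bg, f, col_names = FALSE, progress = FALSE)
    emit(f)
  }

  readr::write_tsv(world$gro, f <- file.path(dir, "gro.tsv"), progress = FALSE)
  emit(f)
  readr::write_tsv(world$marks, f <- file.path(dir, "marks.tsv"), progress = FALSE)
  emit(f)
  readr::write_tsv(world$truth, f <- file.path(dir, "truth.tsv"), progress = FALSE)
  emit(f)

  gl_dir <- file.path(dir, "gene_lists")
  dir.create(gl_dir, showWarnings = FALSE)
  for (ln in names(world$gene_lists)) {
    f <- file.path(gl_dir, paste0(ln, ".txt"))
    writeLines(world$gene_lists[[ln]], f)
    emit(f)
  }

  cfg <- unclass(world$config)
  cfg$spacing_by_class <- as.list(cfg$spacing_by_class)
  f <- file.path(dir, "config.yaml")
  writeLines(yaml::as.yaml(cfg, precision = 15), f); emit(f)
  invisible(written)
}

read_world_file <- function(dir, name) {
  f <- file.path(dir, name)
  if (!file.exists(f)) abort(sprintf("Missing world file: '%s'.", f))
  f
}

#' Read a synthetic world back from a directory
#'
#' Inverse of [write_world()]; reconstructs the in-memory representation
#' (genome as character vector, tracks as per-base numeric vectors, interval
#' tables as tibbles).
#'
#' @param dir Directory written by [write_world()].
#' @return A `synthetic_world` list.
#' @export
read_world <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("World directory '%s' does not exist.", dir))
  fa <- Biostrings::readDNAStringSet(read_world_file(dir, "genome.fa"))
  genome <- setNames(as.character(fa), names(fa))
  chrom_lengths <- setNames(Biostrings::width(fa), names(fa))

  gb <- readr::read_tsv(read_world_file(dir, "genes.bed"),
                        col_names = c("chrom", "start", "end", "gene_id",
                                      "score", "strand"),
                        col_types = "ciicic", progress = FALSE)
  genes <- gb %>%
    select(-"score") %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) %>%
    select("gene_id", "chrom", "start", "end", "strand", "tss")

  nucleosomes <- readr::read_tsv(read_world_file(dir, "nucleosomes.bed"),
                                 col_names = c("chrom", "start", "end", "label"),
                                 col_types = "ciic", progress = FALSE)
  tfbs <- readr::read_tsv(read_world_file(dir, "tfbs.bed"),
                          col_names = c("chrom", "start", "end", "factor",
                                        "score", "strand"),
                          col_types = "ciicic", progress = FALSE) %>%
    select("factor", "chrom", "start", "end", "strand")

  tracks <- list()
  for (f in list.files(dir, pattern = "\\.bedGraph$", full.names = TRUE)) {
    tn <- sub("\\.bedGraph$", "", basename(f))
    bg <- readr::read_tsv(f, col_names = c("chrom", "start", "end", "value"),
                          col_types = "ciid", progress = FALSE)
    tracks[[tn]] <- lapply(split(bg, bg$chrom), function(b) {
      v <- rep(NA_real_, chrom_lengths[[b$chrom[1]]])
      for (i in seq_len(nrow(b))) v[(b$start[i] + 1L):b$end[i]] <- b$value[i]
      v
    })[names(chrom_lengths)]
    names(tracks[[tn]]) <- names(chrom_lengths)
  }

  gro <- readr::read_tsv(read_world_file(dir, "gro.tsv"),
                         col_types = "ccidd", progress = FALSE) %>%
    mutate(replicate = as.integer(.data$replicate))
  marks <- readr::read_tsv(read_world_file(dir, "marks.tsv"),
                           col_types = "ccdd", progress = FALSE)
  truth_f <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_f)) {
    readr::read_tsv(truth_f, col_types = "ccd", progress = FALSE)
  } else {
    tibble(gene_id = character(), class = character(), fold = numeric())
  }

  gl_dir <- file.path(dir, "gene_lists")
  gene_lists <- list()
  if (dir.exists(gl_dir)) {
    for (f in list.files(gl_dir, pattern = "\\.txt$", full.names = TRUE)) {
      gene_lists[[sub("\\.txt$", "", basename(f))]] <- readLines(f)
    }
  }

  cfg_f <- file.path(dir, "config.yaml")
  config <- NULL
  if (file.exists(cfg_f)) {
    raw <- yaml::read_yaml(cfg_f)
    raw$spacing_by_class <- unlist(raw$spacing_by_class)
    config <- do.call(world_config, raw)
  }

  genes$class <- "unchanged"
  genes$class[match(truth$gene_id, genes$gene_id)] <- truth$class

  structure(list(config = config, chrom_lengths = chrom_lengths,
                 genome = genome, genes = genes, gro = gro,
                 nucleosomes = nucleosomes, tfbs = tfbs, tracks = tracks,
                 marks = marks, gene_lists = gene_lists, truth = truth),
            class = "synthetic_world")
}

#' Generate the small fixture world used by the test-suite
#'
#' Writes a compact world (two short chromosomes, 60 genes) to `dir`.
#' Regeneration with the same seed is idempotent: the emitted files are
#' byte-identical across calls.
#'
#' @param dir Output directory.
#' @param seed Integer seed (default 42).
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(dir, seed = 42L) {
  cfg <- world_config(seed = seed, n_chroms = 2L, chrom_length = 70000L,
                      n_genes = 60L)
  write_world(generate_world(cfg), dir)
}
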