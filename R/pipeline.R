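#' Parse a flat pipeline configuration file
#'
#' Sections in square brackets, `key = value` lines, `#` comments. The
#' `[global]` section holds `stages` (comma-separated, in run order) and
#' shared inputs; per-stage sections override or extend.
#'
#' @param path config file.
#' @return nested named list: `config$global$stages`, `config[[stage]]`.
#' @export
parse_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: '", ln, "'",
                             call. = FALSE)
    cfg[[section]][[trimws(kv[1])]] <-
      trimws(paste(kv[-1], collapse = "="))
  }
  cfg
}

PIPELINE_STAGES <- c("initial-process", "derep", "chimera-hook",
                     "community-error", "cluster", "rep-seqs", "diversity")

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in order, each writing into its own
#' subdirectory of `out_dir`, and records a run manifest (package
#' version, parameters, seeds, per-stage read counts; no timestamps, so
#' identical configurations rerun byte-identically). Stage dependencies
#' are validated before any work: `community-error` needs `refs`,
#' `cluster` needs sequences (clustering uses a gap-free alignment of the
#' equal-length filtered reads unless an `aln` file is given), `rep-seqs`
#' and `diversity` need `cluster`. Around the expensive
#' `community-error` stage, reads are dereplicated automatically and the
#' per-read assignments re-replicated ("exploded") afterwards. The
#' optional `chimera-hook` runs a user-supplied external command
#' (`command`, with `{in}` and `{out}` placeholders) and validates that
#' the output is a FASTA subset of its input; no chimera detector is
#' bundled.
#'
#' @param config path to a config file or a nested list from
#'   [parse_pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly a list of per-stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- parse_pipeline_config(config)
  g <- config$global
  if (is.null(g$stages)) stop("config lacks global 'stages'", call. = FALSE)
  stages <- trimws(strsplit(g$stages, ",", fixed = TRUE)[[1]])
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) stop("unknown stage '", bad[1], "'", call. = FALSE)
  opt <- function(stage, key, default = NULL) {
    v <- config[[stage]][[key]]
    if (is.null(v)) v <- g[[key]]
    if (is.null(v)) default else v
  }
  # validate dependencies before any work
  if ("community-error" %in% stages && is.null(opt("community-error", "refs")))
    stop("community-error stage requires 'refs'", call. = FALSE)
  if ("cluster" %in% stages && is.null(opt("cluster", "aln")) &&
      is.null(g$seqs))
    stop("cluster stage requires an alignment ('aln') or input sequences",
         call. = FALSE)
  for (st in intersect(c("rep-seqs", "diversity"), stages)) {
    if (!("cluster" %in% stages)) {
      stop(st, " stage requires the cluster stage", call. = FALSE)
    }
  }
  needs_reads <- c("initial-process", "derep", "chimera-hook",
                   "community-error")
  if (any(stages %in% needs_reads) && is.null(g$seqs))
    stop("config lacks input sequences ('seqs')", call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("package\tampkit %s",
                        as.character(utils::packageVersion("ampkit"))),
                sprintf("stages\t%s", paste(stages, collapse = ",")),
                sprintf("seed\t%s", opt("global", "seed", "NA")))
  results <- list()

  reads <- if (!is.null(g$seqs)) {
    paths <- trimws(strsplit(g$seqs, ",", fixed = TRUE)[[1]])
    do.call(c, lapply(paths, load_reads))
  } else NULL

  for (st in stages) {
    sdir <- file.path(out_dir, st)
    dir.create(sdir, showWarnings = FALSE)
    if (st == "initial-process") {
      tags <- if (!is.null(opt(st, "tags")))
        parse_tag_table(opt(st, "tags")) else NULL
      primers <- primer_set(
        forward = strsplit(opt(st, "fwd_primers"), ",")[[1]],
        reverse = if (!is.null(opt(st, "rev_primers")))
          strsplit(opt(st, "rev_primers"), ",")[[1]] else character(0))
      cfg <- filter_config(
        max_fwd_diff = as.integer(opt(st, "max_fwd_diff", 2)),
        max_rev_diff = as.integer(opt(st, "max_rev_diff", 1)),
        max_n = as.integer(opt(st, "max_ns", 0)),
        min_length = as.integer(opt(st, "min_length", 150)),
        min_rq = as.numeric(opt(st, "min_rq", 20)),
        keep_primer = isTRUE(as.logical(opt(st, "keep_primer", "FALSE"))))
      rep <- process_run(reads, tags, primers, cfg, out_dir = sdir)
      results[[st]] <- rep
      reads <- rep$passed
      manifest <- c(manifest,
                    sprintf("%s\treads_in=%d\treads_out=%d", st,
                            nrow(rep$reads), length(rep$passed)))
    } else if (st == "derep") {
      drp <- dereplicate(reads)
      write_reads(drp$unique, file.path(sdir, "unique.fasta"))
      write_id_map(drp$id_map, file.path(sdir, "ids.map"))
      write_sample_map(drp$sample_map, file.path(sdir, "samples.map"))
      results[[st]] <- drp
      manifest <- c(manifest, sprintf("%s\treads_in=%d\tunique=%d", st,
                                      length(reads), length(drp$unique)))
    } else if (st == "chimera-hook") {
      cmd <- opt(st, "command")
      if (is.null(cmd)) stop("chimera-hook requires 'command'",
                             call. = FALSE)
      fin <- file.path(sdir, "input.fasta")
      fout <- file.path(sdir, "nonchimeric.fasta")
      write_reads(reads, fin)
      cmd <- gsub("{in}", fin, gsub("{out}", fout, cmd, fixed = TRUE),
                  fixed = TRUE)
      status <- system(cmd)
      if (status != 0 || !file.exists(fout)) {
        stop("chimera hook failed (exit ", status, ")", call. = FALSE)
      }
      keep <- load_reads(fout)
      extra <- setdiff(keep$id, reads$id)
      if (length(extra) > 0) {
        stop("chimera hook emitted unknown read '", extra[1], "'",
             call. = FALSE)
      }
      reads <- reads[match(keep$id, reads$id)]
      results[[st]] <- keep$id
      manifest <- c(manifest, sprintf("%s\tkept=%d", st, length(keep)))
    } else if (st == "community-error") {
      refs_reads <- load_reads(opt(st, "refs"))
      refs <- stats::setNames(refs_reads$bases, refs_reads$id)
      ea <- error_analysis(reads, refs)  # dereplicates internally
      write_error_analysis(ea, sdir)
      # exploded per-read assignment table
      utils::write.table(ea$per_read[, c("id", "ref_id", "n_sub", "n_ins",
                                         "n_del")],
                         file.path(sdir, "assignments.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      results[[st]] <- ea
      manifest <- c(manifest,
                    sprintf("%s\treads=%d\terror_rate=%.6g", st,
                            nrow(ea$per_read),
                            summarize_errors(ea)$error_rate))
    } else if (st == "cluster") {
      maln <- if (!is.null(opt(st, "aln"))) {
        load_masked_alignment(trimws(strsplit(opt(st, "aln"), ",")[[1]]))
      } else {
        as_masked_alignment(reads)
      }
      smap <- if (!is.null(opt(st, "sample_map"))) {
        read_sample_map(opt(st, "sample_map"))
      } else if (!is.null(reads)) {
        data.frame(id = reads$id, sample = ifelse(nzchar(reads$sample),
                                                  reads$sample, "all"))
      } else NULL
      cs <- cluster_sequences(
        maln, method = opt(st, "method", "complete"),
        max_cutoff = as.numeric(opt(st, "cutoff", 0.5)),
        step = as.numeric(opt(st, "step", 0.01)),
        sample_map = smap,
        min_overlap = as.integer(opt(st, "min_overlap", 25)))
      write_clust(cs, file.path(sdir, "clusters.clust"))
      results[[st]] <- cs
      results$.maln <- maln
      manifest <- c(manifest,
                    sprintf("%s\tsequences=%d\tlevels=%d", st,
                            sum(cs$sample_sizes), length(cs$levels)))
    } else if (st == "rep-seqs") {
      cut <- as.numeric(opt(st, "cutoff", 0.03))
      reps <- representative_sequences(
        results$cluster, results$.maln, cut,
        min_overlap = as.integer(opt(st, "min_overlap", 25)))
      write_rep_seqs(reps, file.path(sdir, "representatives.fasta"))
      results[[st]] <- reps
      manifest <- c(manifest, sprintf("%s\tclusters=%d", st, nrow(reps)))
    } else if (st == "diversity") {
      cuts <- as.numeric(trimws(
        strsplit(opt(st, "cutoffs", opt(st, "cutoff", "0.03")), ",")[[1]]))
      write_diversity(results$cluster, cuts, sdir)
      results[[st]] <- alpha_diversity(results$cluster, cuts)
      manifest <- c(manifest, sprintf("%s\tcutoffs=%s", st,
                                      paste(cuts, collapse = ",")))
    }
  }
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  results$.maln <- NULL
  invisible(results)
}
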