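#' Configuration for a full pipeline run
#'
#' @param genomes named list of genome inputs: each either a `genome` /
#'   `synthetic_genome` object, a `synthetic_genome_config`, or a list with
#'   `fasta` and `annotation` paths.
#' @param ks integer vector of word lengths (1..11).
#' @param region_classes region classes to analyze.
#' @param reference list with the Markov reference settings: `order`
#'   (0/1), `gc` (fraction), `length` (bp), `replicates`; or `NULL` to skip
#'   reference subtraction.
#' @param tol_strand relative tolerance for strand-pattern calls.
#' @param out_dir output directory.
#' @param seed master seed (simulation + reference).
#' @param plots emit correlation heatmaps (PNG, requires pheatmap).
#' @return a `run_config` list.
#' @export
run_config <- function(genomes, ks = 7,
                       region_classes = c("intronic", "intergenic",
                                          "exonic", "CDS"),
                       reference = list(order = 1, gc = 0.4, length = 1e6,
                                        replicates = 5),
                       tol_strand = 0.25, out_dir = tempfile("strdecomp_run"),
                       seed = 1, plots = FALSE) {
  if (any(ks < 1 | ks > 11)) stop("k values must lie in 1..11")
  if (is.null(names(genomes)))
    names(genomes) <- sprintf("genome%d", seq_along(genomes))
  structure(list(genomes = genomes, ks = as.integer(ks),
                 region_classes = region_classes, reference = reference,
                 tol_strand = tol_strand, out_dir = out_dir, seed = seed,
                 plots = plots),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full spectrum-correlation pipeline
#'
#' Loads or generates the configured genomes, derives regions, computes
#' per-genome per-region spectra for every `k`, builds genome-genome
#' correlation matrices per region pair, subtracts Markov reference
#' correlations, and emits contribution tables (STR unit-length groups and
#' extended base-code families), 0-mm/1-mm ratio tables, strand-pattern
#' calls and deviation profiles with rule coverage. All tables are written
#' as TSV with JSON sidecars plus a manifest recording the configuration
#' hash and seeds; outputs are a pure function of (inputs, config, seed).
#'
#' @param config a `run_config`.
#' @return (invisibly) list with the in-memory results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  genomes <- stage("load", lapply(config$genomes, function(g) {
    if (inherits(g, "genome")) g
    else if (inherits(g, "synthetic_genome_config")) generate_genome(g)
    else if (is.list(g) && !is.null(g$fasta)) load_genome(g$fasta, g$annotation)
    else stop("unrecognized genome input")
  }))
  gnames <- names(genomes)

  regions <- stage("regions", lapply(genomes, derive_regions))
  comp <- stage("composition", {
    do.call(rbind, lapply(gnames, function(nm) {
      g <- genomes[[nm]]
      cbind(genome = nm,
            region_composition(regions[[nm]],
                               sum(Biostrings::width(g$sequences))))
    }))
  })
  files <- c(composition = write_tsv(comp,
                                     file.path(config$out_dir,
                                               "region_composition.tsv")))

  rc <- config$region_classes
  results <- list(composition = comp)
  for (k in config$ks) {
    kdir <- file.path(config$out_dir, sprintf("k%d", k))
    dir.create(kdir, showWarnings = FALSE)
    spectra <- stage("spectra", {
      out <- list()
      for (nm in gnames) for (cl in rc) {
        sp <- compute_spectrum(
          extract_sequences(regions[[nm]][[cl]], genomes[[nm]]$sequences), k,
          label = paste(nm, cl))
        out[[paste(nm, cl, sep = ".")]] <- sp
        write_spectrum_tsv(sp, file.path(kdir,
                                         sprintf("spectrum_%s_%s.tsv", nm, cl)),
                           zeros = FALSE)
      }
      out
    })

    ## reference ensemble
    ref <- NULL
    if (!is.null(config$reference)) {
      ref <- stage("reference", build_reference_ensemble(
        markov_model(order = config$reference$order, gc = config$reference$gc),
        k, config$reference$length, config$reference$replicates,
        seed = config$seed + k))
    }

    ## genome x genome correlation matrix per region pair + mean table
    pairs <- expand.grid(a = rc, b = rc, stringsAsFactors = FALSE)
    pairs <- pairs[as.integer(factor(pairs$a, rc)) <=
                     as.integer(factor(pairs$b, rc)), ]
    mean_rows <- list()
    corr_mats <- list()
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs$a[pi]; b <- pairs$b[pi]
      m <- matrix(NA_real_, length(gnames), length(gnames),
                  dimnames = list(gnames, gnames))
      for (i in seq_along(gnames)) for (j in seq_along(gnames)) {
        m[i, j] <- pearson_correlation(
          spectra[[paste(gnames[i], a, sep = ".")]],
          spectra[[paste(gnames[j], b, sep = ".")]])$r
      }
      corr_mats[[paste(a, b, sep = "-")]] <- m
      write_tsv(cbind(genome = rownames(m), as.data.frame(m)),
                file.path(kdir, sprintf("corr_%s_%s.tsv", a, b)))
      if (!is.null(ref)) {
        vals <- if (a == b) m[upper.tri(m, diag = FALSE)] else as.numeric(m)
        if (length(vals) == 0) vals <- diag(m)  # single genome, same class
        mean_rows[[pi]] <- mean_correlation_with_reference(
          vals, ref, label = paste(a, b, sep = "-"))
      }
      if (config$plots && requireNamespace("pheatmap", quietly = TRUE)) {
        grDevices::png(file.path(kdir, sprintf("corr_%s_%s.png", a, b)),
                       width = 600, height = 600)
        pheatmap::pheatmap(pmax(m, -0.4), cluster_rows = FALSE,
                           cluster_cols = FALSE,
                           main = sprintf("%s vs %s (k=%d)", a, b, k))
        grDevices::dev.off()
      }
    }
    if (length(mean_rows))
      write_tsv(do.call(rbind, mean_rows),
                file.path(kdir, "mean_correlation.tsv"))

    ## contribution tables over genome pairs for each region pair
    contrib_rows <- list()
    fam_rows <- list()
    gp <- if (length(gnames) > 1) utils::combn(length(gnames), 2) else
      matrix(c(1, 1), nrow = 2)
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs$a[pi]; b <- pairs$b[pi]
      gb <- lapply(seq_len(ncol(gp)), function(q) {
        x <- spectra[[paste(gnames[gp[1, q]], a, sep = ".")]]
        y <- spectra[[paste(gnames[gp[2, q]], b, sep = ".")]]
        list(b = grouped_contributions(x, y, "str_b"),
             fam = grouped_contributions(x, y, "families"))
      })
      avg <- function(dfs) {
        out <- dfs[[1]]
        out$contribution <- rowMeans(
          vapply(dfs, function(d) d$contribution, numeric(nrow(out))))
        out
      }
      bt <- avg(lapply(gb, `[[`, "b"))
      ft <- avg(lapply(gb, `[[`, "fam"))
      contrib_rows[[pi]] <- cbind(pair = paste(a, b, sep = "-"), bt)
      fam_rows[[pi]] <- cbind(pair = paste(a, b, sep = "-"), ft)
    }
    write_tsv(do.call(rbind, contrib_rows),
              file.path(kdir, "contributions_str_b.tsv"))
    write_tsv(do.call(rbind, fam_rows),
              file.path(kdir, "contributions_families.tsv"))

    ## per-word 0mm/1mm ratio table + strand calls + deviation profiles,
    ## focused on the intronic-intergenic comparison when available
    focus <- if (all(c("intronic", "intergenic") %in% rc))
      c("intronic", "intergenic") else c(rc[1], rc[length(rc)])
    b12 <- c(set_words(enumerate_str_words(k, 1)),
             set_words(enumerate_str_words(k, 2)))
    ratio_tabs <- lapply(seq_len(ncol(gp)), function(q)
      contribution_ratio_table(
        spectra[[paste(gnames[gp[1, q]], focus[1], sep = ".")]],
        spectra[[paste(gnames[gp[2, q]], focus[2], sep = ".")]], b12))
    rt <- ratio_tabs[[1]]
    rt$c0 <- rowMeans(vapply(ratio_tabs, function(d) d$c0, numeric(nrow(rt))))
    rt$c1 <- rowMeans(vapply(ratio_tabs, function(d) d$c1, numeric(nrow(rt))))
    rt$ratio <- ifelse(rt$c0 != 0, rt$c1 / rt$c0, NA_real_)
    rt$ratio_defined <- rt$c0 != 0
    write_tsv(rt, file.path(kdir, "mismatch_ratio.tsv"))

    word_contrib <- stats::setNames(rt$c0, rt$word)
    fams <- word_family_sets(k)
    calls <- do.call(rbind, lapply(b12, function(w) {
      bw <- minimal_period(w)
      pc <- classify_strand_pattern(word_contrib, w, b = bw,
                                    tol = config$tol_strand)
      data.frame(word = w, b = bw, call = pc$call,
                 value = pc$values["word"], inv_compl = pc$values["inv_compl"],
                 shift = pc$values["shift"], row.names = NULL)
    }))
    write_tsv(calls, file.path(kdir, "strand_patterns.tsv"))

    ## deviation profiles per family word, averaged across genomes over
    ## pooled intronic+intergenic sequences
    profiles <- lapply(b12, function(w) {
      per_genome <- lapply(gnames, function(nm) {
        sp <- compute_spectrum(c(
          as.character(extract_sequences(regions[[nm]][[focus[1]]],
                                         genomes[[nm]]$sequences)),
          as.character(extract_sequences(regions[[nm]][[focus[2]]],
                                         genomes[[nm]]$sequences))), k)
        deviation_profile(sp, w)
      })
      pcts <- lapply(per_genome, function(p)
        p$percent[order(names(p$percent))])
      ok <- !vapply(per_genome, function(p) p$empty, logical(1))
      if (!any(ok)) return(per_genome[[1]])
      avg <- rowMeans(do.call(cbind, pcts[ok]))
      ord <- order(avg, decreasing = TRUE)
      structure(list(word = w, percent = avg[ord], counts = avg[ord],
                     total = sum(ok), empty = FALSE),
                class = "deviation_profile")
    })
    cov <- rule_coverage(profiles)
    write_tsv(cov$detail, file.path(kdir, "deviation_rules.tsv"))
    jsonlite::write_json(cov[c("n", "covered", "ambiguous", "uncovered")],
                         file.path(kdir, "rule_coverage.json"),
                         auto_unbox = TRUE, digits = NA)
    prof_df <- do.call(rbind, lapply(profiles, function(p)
      data.frame(word = p$word,
                 base = names(p$percent), percent = unname(p$percent))))
    write_tsv(prof_df, file.path(kdir, "deviation_profiles.tsv"))

    results[[sprintf("k%d", k)]] <- list(
      spectra = spectra, correlations = corr_mats,
      mean_correlation = if (length(mean_rows)) do.call(rbind, mean_rows),
      contributions_b = do.call(rbind, contrib_rows),
      contributions_families = do.call(rbind, fam_rows),
      ratio_table = rt, strand_calls = calls, rule_coverage = cov)
  }

  manifest <- list(
    package = "strdecomp",
    version = as.character(utils::packageVersion("strdecomp")),
    seed = config$seed, ks = config$ks, regions = rc,
    genomes = gnames,
    reference = config$reference,
    config_hash = unname(config_hash(config)),
    files = list.files(config$out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$out_dir <- config$out_dir
  invisible(results)
}

## md5 of the canonical JSON rendering of the configuration
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  safe <- config
  safe$genomes <- lapply(safe$genomes, function(g) {
    if (inherits(g, "synthetic_genome_config")) unclass(g)
    else if (inherits(g, "genome")) list(chromosomes = as.list(
      stats::setNames(g$annotation$chromosomes$length,
                      g$annotation$chromosomes$id)))
    else g
  })
  writeLines(jsonlite::toJSON(safe, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  as.character(tools::md5sum(tmp))
}
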