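# Reporting: deterministic SVG ideograms, Table-style karyotype reports,
# profile/dissimilarity/tree exports, and the run configuration container.

#' Plot a karyotype ideogram as a deterministic SVG
#'
#' Draws one bar per chromosome, ordered longest to shortest, with bar
#' height proportional to relative chromosome length, a centromere mark at
#' the long/short arm boundary, and 5S (TAMRA) sites as filled circles at
#' their arm positions. The SVG is generated textually, so identical input
#' yields byte-identical output.
#'
#' @param table Measurement table (non-empty).
#' @param sites Optional signal-site data frame (columns `chromosome_id`,
#'   `channel`, `arm`, `position_fraction`).
#' @param path Output `.svg` path.
#' @param title Optional plot title.
#' @return `path`, invisibly.
#' @export
plot_ideogram <- function(table, sites = NULL, path, title = NULL) {
  if (is.null(table) || nrow(table) == 0)
    kf_validation_error("plot_ideogram requires a non-empty table")
  tab <- order_by_length(table)
  n <- nrow(tab)
  rel <- tab$relative_length
  bar_w <- 18; gap <- 8; top <- 30; bottom <- 20
  plot_h <- 220
  height <- top + plot_h + bottom
  width <- 40 + n * (bar_w + gap)
  scale <- plot_h / max(rel)
  fmt <- function(x) formatC(x, format = "f", digits = 2)

  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height),
           '<rect width="100%" height="100%" fill="white"/>')
  if (!is.null(title))
    out <- c(out, sprintf('<text x="%d" y="18" font-size="13" font-family="sans-serif">%s</text>',
                          20, title))
  for (i in seq_len(n)) {
    x <- 20 + (i - 1) * (bar_w + gap)
    h <- rel[i] * scale
    y <- top + plot_h - h
    short_frac <- tab$short_arm[i] / tab$total_length[i]
    # bars are drawn short arm up, the conventional karyogram orientation
    y_cen <- y + short_frac * h
    out <- c(out,
      sprintf('<rect x="%s" y="%s" width="%d" height="%s" fill="#9db8d9" stroke="#334"/>',
              fmt(x), fmt(y), bar_w, fmt(h)),
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000" stroke-width="2"/>',
              fmt(x - 2), fmt(y_cen), fmt(x + bar_w + 2), fmt(y_cen)),
      sprintf('<text x="%s" y="%d" font-size="9" font-family="sans-serif" text-anchor="middle">%d</text>',
              fmt(x + bar_w / 2), top + plot_h + 12, i))
    if (!is.null(sites) && nrow(sites)) {
      ss <- sites[sites$chromosome_id == tab$chromosome_id[i] &
                    sites$channel == "TAMRA", , drop = FALSE]
      for (j in seq_len(nrow(ss))) {
        f <- ss$position_fraction[j]
        y_site <- if (identical(ss$arm[j], "short"))
          y_cen - f * (y_cen - y) else y_cen + f * (y + h - y_cen)
        out <- c(out,
          sprintf('<circle cx="%s" cy="%s" r="3.2" fill="#d33" stroke="#800"/>',
                  fmt(x + bar_w / 2), fmt(y_site)))
      }
    }
  }
  out <- c(out, '</svg>')
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Write the full analysis report for a set of species
#'
#' Emits, under `out_dir`: `karyotype_table.tsv` (columns Species,
#' Karyotype, Cytotype, Arm Ratio — the interchromosomal longest/shortest
#' ratio, printed to four decimals), one `signals_<species>.tsv` per
#' species with signal data, `profiles.json`, `dissimilarity.tsv`,
#' `tree.nwk`, and `manifest.json` recording the configuration, seeds and
#' package version.
#'
#' @param results Named list (by species id) of lists with elements
#'   `karyotype` (a `karyotype_result`), optionally `signals` (site data
#'   frame) and `profile` (a `signal_profile`).
#' @param out_dir Output directory (created if needed).
#' @param config Optional [run_config()] recorded in the manifest.
#' @param linkage,weights Clustering options used when >= 2 profiles are
#'   present.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, out_dir, config = NULL,
                         linkage = "average",
                         weights = c(w_n = 1.0, w_c = 0.5, w_h = 0.25)) {
  if (!length(results))
    kf_validation_error("write_report requires at least one result")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    kf_io_error("cannot create output directory %s", out_dir)
  written <- character(0)

  kary <- data.frame(
    Species = vapply(results, function(r) r$karyotype$species_id, ""),
    Karyotype = vapply(results, function(r) r$karyotype$formula_string, ""),
    Cytotype = vapply(results, function(r) r$karyotype$cytotype, ""),
    `Arm.Ratio` = vapply(results, function(r)
      formatC(r$karyotype$ls_ratio, format = "f", digits = 4), ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(kary)[4] <- "Arm Ratio"
  kt_path <- file.path(out_dir, "karyotype_table.tsv")
  utils::write.table(kary, kt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(written, kt_path)

  profiles <- list()
  for (sp in names(results)) {
    r <- results[[sp]]
    if (!is.null(r$signals) && nrow(r$signals)) {
      sp_path <- file.path(out_dir, sprintf("signals_%s.tsv", sp))
      cols <- intersect(c("chromosome_id", "channel", "arm",
                          "position_fraction", "category", "intensity"),
                        names(r$signals))
      utils::write.table(r$signals[, cols], sp_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written <- c(written, sp_path)
    }
    if (!is.null(r$profile)) profiles[[sp]] <- r$profile
  }

  if (length(profiles)) {
    pr_path <- file.path(out_dir, "profiles.json")
    jsonlite::write_json(
      lapply(profiles, function(p) list(
        species_id = p$species_id, n_pairs_5S = p$n_pairs_5S,
        category_counts = as.list(p$category_counts),
        heteromorphic_pairs = p$heteromorphic_pairs)),
      pr_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, pr_path)
  }
  if (length(profiles) >= 2) {
    dend <- cluster_profiles(unname(profiles), linkage = linkage,
                             weights = weights,
                             newick_path = file.path(out_dir, "tree.nwk"))
    dm_path <- file.path(out_dir, "dissimilarity.tsv")
    utils::write.table(dend$dist, dm_path, sep = "\t", quote = FALSE,
                       col.names = NA)
    written <- c(written, dm_path, file.path(out_dir, "tree.nwk"))
  }

  manifest <- list(
    package = "karyofish",
    version = as.character(utils::packageVersion("karyofish")),
    config = if (is.null(config)) NULL else unclass(config),
    species = names(results),
    linkage = linkage,
    weights = as.list(weights)
  )
  mf_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, digits = NA)
  written <- c(written, mf_path)
  invisible(written)
}

#' Run configuration
#'
#' Collects every tunable pipeline parameter with its documented default.
#' A configuration round-trips losslessly through the flat `key = value`
#' file format of [write_run_config()] / [read_run_config()].
#'
#' @param species Character vector of species ids.
#' @param seed Base integer seed.
#' @param noise_cv Measurement-noise coefficient of variation.
#' @param linkage Clustering linkage (`"average"` or `"single"`).
#' @param w_n,w_c,w_h Profile-dissimilarity weights.
#' @param pixel_size Rendering resolution (micrometres per pixel).
#' @param out_dir Output directory.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(species = species_ids(), seed = 1L, noise_cv = 0,
                       linkage = "average", w_n = 1.0, w_c = 0.5,
                       w_h = 0.25, pixel_size = 0.04, out_dir = "results") {
  structure(as.list(environment()), class = "run_config")
}

#' Write a run configuration as flat `key = value` text
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  fmt1 <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15)
  }
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(vapply(v, fmt1, ""), collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path Config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) kf_io_error("no such config file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) kf_validation_error("unparsable config line: %s", ln)
    vals <- trimws(strsplit(kv[3], ",")[[1]])
    parsed <- vapply(vals, function(v) {
      if (grepl('^".*"$', v)) list(gsub('^"|"$', "", v))
      else if (v %in% c("true", "false")) list(v == "true")
      else list(as.numeric(v))
    }, vector("list", 1))
    cfg[[kv[2]]] <- unlist(parsed, use.names = FALSE)
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
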