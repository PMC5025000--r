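#' Read and write XYZ trajectory files
#'
#' Conformations are serialized as standard multi-frame XYZ: an atom count
#' line, a comment line, then one `C x y z` line per bead, coordinates in
#' nm. `read_xyz()` returns a list of coordinate matrices (one per frame).
#'
#' @param frames A coordinate matrix, a [dna_chain()], a `chain_ensemble`,
#'   or a list of such.
#' @param path Output (input) file path.
#' @param comment Comment-line prefix; the frame index is appended.
#' @return `write_xyz()` the path invisibly; `read_xyz()` a list of N x 3
#'   matrices.
#' @export
write_xyz <- function(frames, path, comment = "knotdna frame") {
  frames <- as_frame_list(frames)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    m <- frames[[i]]
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("%s %d", comment, i), con)
    writeLines(sprintf("C %.8f %.8f %.8f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1 || i + 1 + n > length(lines) + 0)
      stop(sprintf("malformed XYZ frame header at line %d", i), call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(m)))
      stop(sprintf("malformed coordinates in XYZ frame starting at line %d", i),
           call. = FALSE)
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("no frames found in XYZ file", call. = FALSE)
  frames
}

as_frame_list <- function(frames) {
  if (is.matrix(frames)) return(list(frames))
  if (inherits(frames, "dna_chain")) return(list(frames$coords))
  if (inherits(frames, "chain_ensemble") || is.list(frames))
    return(lapply(frames, function(f)
      if (inherits(f, "dna_chain")) f$coords else as.matrix(f)))
  stop("cannot interpret `frames` as conformations", call. = FALSE)
}

#' Minimal PDB writer (CA pseudo-atoms)
#'
#' Writes beads as CA pseudo-atoms of consecutive residues for quick
#' visualization; coordinates are written in Angstrom (nm x 10).
#'
#' @param chain A [dna_chain()] or coordinate matrix (nm).
#' @param path Output file path.
#' @export
write_pdb <- function(chain, path) {
  co <- if (inherits(chain, "dna_chain")) chain$coords else as.matrix(chain)
  ang <- co * 10
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(ang)), seq_len(nrow(ang)), ang[, 1], ang[, 2], ang[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a minimal PDB file into a frame list
#'
#' Extracts ATOM/HETATM records and converts Angstrom to nm; one frame per
#' MODEL block (or a single frame if no MODEL records).
#'
#' @param path PDB file path.
#' @return A list of N x 3 coordinate matrices (nm).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- list()
  flush <- function() {
    if (length(cur) > 0) models[[length(models) + 1L]] <<- do.call(rbind, cur)
    cur <<- list()
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag %in% c("ATOM  ", "HETATM")) {
      cur[[length(cur) + 1L]] <- as.numeric(c(substr(ln, 31, 38),
                                              substr(ln, 39, 46),
                                              substr(ln, 47, 54))) / 10
    } else if (trimws(tag) == "ENDMDL") flush()
  }
  flush()
  if (length(models) == 0) stop("no coordinates found in PDB file", call. = FALSE)
  models
}

# --------------------------------------------------------------------------
# pipeline commands

default_config <- function() {
  list(n_beads = NULL, n_bp = NULL, g = 11.673, d = 4.465,
       n_samples = 200L, sampling_interval = 2L, burn_in = 100L, seed = 1L,
       move_mix = list(pivot = 0.4, crankshaft = 0.3, mos_inversion = 0.1,
                       mos_reflection = 0.1, mos_interchange = 0.1),
       locate = FALSE, write_trajectory = FALSE)
}

#' Load a run configuration (YAML or JSON)
#'
#' @param x A file path (`.yaml`/`.yml`/`.json`) or a named list; missing
#'   fields are filled from defaults. Either `n_beads` or `n_bp` must be
#'   given.
#' @return A validated configuration list.
#' @export
load_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  } else if (is.list(x)) x else
    stop("`x` must be a file path or a list", call. = FALSE)
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(default_config(), cfg)
  errs <- character()
  if (is.null(cfg$n_beads) && is.null(cfg$n_bp))
    errs <- c(errs, "one of `n_beads` or `n_bp` is required")
  if (!is.numeric(cfg$g) || cfg$g < 0) errs <- c(errs, "`g` must be >= 0")
  if (!is.numeric(cfg$d) || cfg$d <= 0) errs <- c(errs, "`d` must be > 0")
  if (cfg$n_samples < 1) errs <- c(errs, "`n_samples` must be >= 1")
  if (cfg$sampling_interval < 1) errs <- c(errs, "`sampling_interval` must be >= 1")
  if (cfg$burn_in < 0) errs <- c(errs, "`burn_in` must be >= 0")
  mm <- unlist(cfg$move_mix)
  if (abs(sum(mm) - 1) > 1e-8) errs <- c(errs, "`move_mix` must sum to 1")
  if (length(errs) > 0)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  cfg
}

config_params <- function(cfg) model_params(g = cfg$g, d = cfg$d)
config_moves <- function(cfg) do.call(move_set, as.list(unlist(cfg$move_mix)))
config_n_beads <- function(cfg) {
  if (!is.null(cfg$n_beads)) as.integer(cfg$n_beads)
  else beads_for_bp(cfg$n_bp, config_params(cfg))
}

#' Run a simulation with per-frame knot analysis
#'
#' Samples an ensemble, classifies the knot state of every frame, and (when
#' `out_dir` is given) writes the trajectory (XYZ), the per-frame knot table
#' (TSV), an aggregated summary (TSV) and a reproducibility manifest (JSON)
#' listing the configuration, seeds and output checksums.
#'
#' @param config A configuration list or YAML/JSON path; see [load_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip all
#'   file output.
#' @return Invisibly, a list with `frames_table` (per-frame tibble),
#'   `summary` (one-row tibble) and `manifest`.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  params <- config_params(cfg)
  moves <- config_moves(cfg)
  n <- config_n_beads(cfg)
  ens <- sample_ensemble(params, n, cfg$n_samples,
                         sampling_interval = cfg$sampling_interval,
                         burn_in = cfg$burn_in, seed = cfg$seed,
                         moves = moves)
  frames_table <- dplyr::bind_rows(purrr::imap(ens, function(ch, i) {
    dplyr::bind_cols(tibble::tibble(frame = i),
                     analyze_chain(ch, params = params,
                                   seed = cfg$seed + i, locate = cfg$locate))
  }))
  summary <- summarize_frames(frames_table, n, params, cfg)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    if (isTRUE(cfg$write_trajectory)) {
      write_xyz(ens, file.path(out_dir, "trajectory.xyz"))
      files <- c(files, "trajectory.xyz")
    }
    write_tsv(frames_table, file.path(out_dir, "frames.tsv"))
    write_tsv(summary, file.path(out_dir, "summary.tsv"))
    files <- c(files, "frames.tsv", "summary.tsv")
    manifest <- write_manifest(out_dir, cfg, files)
  }
  invisible(list(frames_table = frames_table, summary = summary,
                 manifest = manifest))
}

summarize_frames <- function(frames_table, n, params, cfg) {
  labs <- frames_table$knot_label
  p_label <- table(labs) / length(labs)
  base <- tibble::tibble(
    n_beads = as.integer(n),
    bp = bp_for_beads(n, params),
    n_samples = length(labs),
    p_knot = mean(labs != "0_1"),
    se = blocked_bootstrap_se(labs != "0_1", seed = cfg$seed),
    p_unknot = mean(labs == "0_1"))
  probs <- tibble::as_tibble(as.list(setNames(
    as.numeric(p_label), paste0("p_", names(p_label)))))
  dplyr::bind_cols(base, probs[setdiff(names(probs), "p_0_1")])
}

write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}

write_manifest <- function(out_dir, cfg, files) {
  manifest <- list(
    package = "knotdna",
    version = as.character(utils::packageVersion("knotdna")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg,
    files = lapply(setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Stand-alone knot analysis of a coordinate file
#'
#' Reads a multi-frame XYZ (or minimal PDB) file and emits the per-frame
#' knot table. Malformed frames are skipped with a warning; if every frame
#' fails, an error is raised.
#'
#' @param path Input coordinate file (`.xyz`, `.pdb`).
#' @param params Optional [model_params()] for bp conversion of knot sizes.
#' @param seed Integer seed for projections.
#' @param locate Localize knotted regions.
#' @param out Optional TSV output path.
#' @return A tibble with one row per frame.
#' @export
analyze_file <- function(path, params = NULL, seed = 1L, locate = FALSE,
                         out = NULL) {
  frames <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) read_pdb(path)
            else read_xyz(path)
  rows <- purrr::imap(frames, function(m, i) {
    tryCatch(
      dplyr::bind_cols(tibble::tibble(frame = i),
                       analyze_chain(m, params = params, seed = seed + i,
                                     locate = locate)),
      error = function(e) {
        warning(sprintf("frame %d skipped: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) stop("all frames failed knot analysis", call. = FALSE)
  if (!is.null(out)) write_tsv(tab, out)
  tab
}

#' Knotting probability as a function of DNA length
#'
#' Runs the sampler at a series of chain lengths, assembles the knotting
#' curve P_knot(bp) with its complement P_unknot(bp), and estimates the
#' unknotting length B0 (the bp count where P_unknot = 1/e) when the series
#' brackets that crossing.
#'
#' @param lengths_bp DNA lengths in base pairs (>= 2 values).
#' @param params A [model_params()].
#' @param ... Passed to [estimate_knotting_probability()] (`n_samples`,
#'   `sampling_interval`, `burn_in`, `moves`, ...).
#' @param seed Integer seed; length k uses `seed + k`.
#' @return A tibble of class `knotting_curve` (columns as in
#'   [estimate_knotting_probability()]) with attribute `B0` (bp, or `NA` if
#'   the 1/e crossing is not bracketed).
#' @export
knotting_curve <- function(lengths_bp, params = dna_params(), seed = 1L, ...) {
  stopifnot(length(lengths_bp) >= 2)
  rows <- purrr::imap(lengths_bp, function(bp, k) {
    n <- beads_for_bp(bp, params)
    estimate_knotting_probability(model_params(g = params$g, d = 1),
                                  n_beads = n, seed = seed + k, ...)
  })
  out <- dplyr::bind_rows(rows)
  out$bp <- as.integer(lengths_bp)  # report requested lengths, N from mapping
  b0 <- tryCatch(estimate_unknotting_length(out), error = function(e) NA_real_)
  attr(out, "B0") <- b0
  class(out) <- c("knotting_curve", class(out))
  out
}
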