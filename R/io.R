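# File formats and run configuration: extended-XYZ trajectories, geometry
# input (XYZ / PDB), YAML run configuration.

format_meta <- function(metadata) {
  if (length(metadata) == 0) return("")
  paste(vapply(names(metadata), function(k)
    sprintf("%s=%.10g", k, as.numeric(metadata[[k]])), character(1)),
    collapse = " ")
}

parse_meta <- function(line) {
  line <- trimws(line)
  if (line == "") return(list())
  toks <- strsplit(line, "\\s+")[[1]]
  kv <- grep("=", toks, value = TRUE)
  out <- list()
  for (t in kv) {
    p <- strsplit(t, "=", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(p[2]))
    out[[p[1]]] <- if (is.na(v)) p[2] else v
  }
  out
}

#' Write geometry frames as extended XYZ
#'
#' One block per frame: atom-count line, a comment line carrying `key=value`
#' metadata (time, energies, coupling, oscillator strength, ...), then one
#' `element x y z` row per atom.
#'
#' @param frames a single `shb_geometry` or a list of them (e.g. from
#'   [trajectory_frames()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "shb_geometry")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in frames) {
    writeLines(as.character(nrow(g$coords)), con)
    writeLines(format_meta(g$metadata), con)
    writeLines(sprintf("%-2s %15.8f %15.8f %15.8f", g$elements,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ file
#'
#' @param path input file.
#' @return list of `shb_geometry` frames, each with its parsed metadata.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || all(trimws(lines) == ""))
    stop("empty trajectory: ", path)
  frames <- list()
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    frame_no <- frame_no + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      stop("malformed frame header at line ", i, " (frame ", frame_no,
           "): expected an atom count")
    if (i + 1L + nat > length(lines))
      stop("frame ", frame_no, " (line ", i, ") declares ", nat,
           " atoms but the file ends early")
    meta <- parse_meta(lines[i + 1L])
    rows <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop("malformed atom record at line ", i + 1L + bad[1],
           " in frame ", frame_no)
    el <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("non-numeric coordinates in frame ", frame_no)
    frames[[frame_no]] <- geometry(el, xyz, metadata = meta)
    i <- i + 2L + nat
  }
  frames
}

#' Read a single geometry from an XYZ or PDB file
#'
#' XYZ files are parsed with [read_xyz()] (first frame); PDB files through
#' the `bio3d` reader, taking element symbols from the element column (or the
#' first letter of the atom name when absent).
#'
#' @param path file ending in `.xyz` or `.pdb`.
#' @return an `shb_geometry`.
#' @export
read_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") return(read_xyz(path)[[1]])
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    el <- trimws(pdb$atom$elesy)
    if (any(is.na(el) | el == ""))
      el <- toupper(substr(trimws(pdb$atom$elety), 1, 1))
    return(geometry(el, cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)))
  }
  stop("unsupported geometry format: .", ext)
}

#' Default configuration for the full analysis protocol
#'
#' @param ... named overrides of the defaults.
#' @return list of class `run_config`: `conditions` (data.frame of
#'   `hb_length` and `label`), `replicas`, `seed_base`, `equil_fs`,
#'   `excited_fs`, `fes_fs`, `dt_fs`, `temperature`, `n_frames_average`,
#'   `bandwidth_ev`, `surface` (parameter overrides as a named list).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    conditions = data.frame(
      hb_length = c(2.5, 3.0, 3.5, 4.5),
      label = c("dimer-SHB", "dimer-3.0", "dimer-3.5", "dimer-4.5"),
      stringsAsFactors = FALSE),
    replicas = 5L,
    seed_base = 1L,
    equil_fs = 3000,
    excited_fs = 1000,
    fes_fs = 20000,
    dt_fs = 0.5,
    temperature = 300,
    n_frames_average = 25L,
    bandwidth_ev = ry_to_ev(0.003),
    surface = list()
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  for (f in c("equil_fs", "excited_fs", "fes_fs"))
    if (abs(cfg[[f]] / cfg$dt_fs - round(cfg[[f]] / cfg$dt_fs)) > 1e-9)
      stop("dt_fs must divide ", f)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$conditions <- as.list(as.data.frame(x$conditions))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()] (or hand-edited).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$conditions <- data.frame(hb_length = x$conditions$hb_length,
                             label = x$conditions$label,
                             stringsAsFactors = FALSE)
  do.call(default_run_config, x)
}
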