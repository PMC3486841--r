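#' Construct a trajectory object
#'
#' A trajectory is an ordered set of coordinate frames sharing one topology
#' (atom identities) plus timing metadata. Frames are 0-based internally;
#' frame `i` is at time `t0_ps + i * dt_ps`. PDB files carry no time record,
#' so the frame interval is supplied as metadata (default 10 ps).
#'
#' @param topology data.frame with columns `serial`, `name`, `residue_name`,
#'   `chain`, `residue_seq` (residue numbering preserved verbatim, never
#'   renumbered).
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames`, in
#'   Angstrom.
#' @param dt_ps frame interval in ps (> 0).
#' @param t0_ps time of the first frame in ps.
#' @return object of class `trajectory`.
#' @export
new_trajectory <- function(topology, coords, dt_ps = 10, t0_ps = 0) {
  stopifnot(is.data.frame(topology))
  req <- c("serial", "name", "residue_name", "chain", "residue_seq")
  missing_cols <- setdiff(req, names(topology))
  if (length(missing_cols) > 0L) {
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[3] < 1L) stop("trajectory must have at least one frame")
  if (dim(coords)[1] != nrow(topology)) {
    stop("coords atom count (", dim(coords)[1], ") does not match topology (",
         nrow(topology), ")")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.numeric(dt_ps) || length(dt_ps) != 1L || dt_ps <= 0) {
    stop("dt_ps must be a single positive number")
  }
  if (any(!nzchar(topology$name))) stop("atom names must be non-empty")
  structure(
    list(topology = topology, coords = coords,
         dt_ps = as.numeric(dt_ps), t0_ps = as.numeric(t0_ps)),
    class = "trajectory"
  )
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Frame times in ps
#' @param traj a `trajectory`.
#' @return numeric vector, `t0_ps + (0:(n-1)) * dt_ps`.
#' @export
frame_times <- function(traj) traj$t0_ps + (seq_len(n_frames(traj)) - 1L) * traj$dt_ps

#' Extract one frame
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return list with `topology` and an `n_atoms x 3` coordinate matrix `xyz`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  list(topology = traj$topology, xyz = traj$coords[, , i, drop = TRUE])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms, %d frames, dt = %g ps (t0 = %g ps)\n",
              nrow(x$topology), n_frames(x), x$dt_ps, x$t0_ps))
  invisible(x)
}

# Parse ATOM/HETATM lines (wwPDB v3.3 fixed columns). Returns a data.frame
# with topology columns + x, y, z + source line numbers. Altloc other than
# blank/'A' is dropped; insertion codes are rejected outright (fixtures and
# MD snapshots never carry them, and silent renumbering would be worse).
parse_atom_lines <- function(lines, line_numbers) {
  altloc <- substr(lines, 17, 17)
  keep <- altloc %in% c("", " ", "A")
  lines <- lines[keep]
  line_numbers <- line_numbers[keep]
  if (length(lines) == 0L) {
    return(data.frame(serial = integer(), name = character(),
                      residue_name = character(), chain = character(),
                      residue_seq = integer(), x = numeric(), y = numeric(),
                      z = numeric(), line = integer(),
                      stringsAsFactors = FALSE))
  }
  icode <- substr(lines, 27, 27)
  bad_icode <- which(!icode %in% c("", " "))
  if (length(bad_icode) > 0L) {
    stop("insertion codes are not supported (line ",
         line_numbers[bad_icode[1]], ")")
  }
  num_field <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) | !nzchar(trimws(s)))
    if (length(bad) > 0L) {
      stop("unparseable ", what, " field (line ", line_numbers[bad[1]], ")")
    }
    v
  }
  data.frame(
    serial = as.integer(num_field(substr(lines, 7, 11), "serial")),
    name = trimws(substr(lines, 13, 16)),
    residue_name = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    residue_seq = as.integer(num_field(substr(lines, 23, 26), "residue number")),
    x = num_field(substr(lines, 31, 38), "x coordinate"),
    y = num_field(substr(lines, 39, 46), "y coordinate"),
    z = num_field(substr(lines, 47, 54), "z coordinate"),
    line = line_numbers,
    stringsAsFactors = FALSE
  )
}

#' Read a multi-model PDB file as a trajectory
#'
#' One frame per MODEL/ENDMDL block; a file without MODEL records yields a
#' single frame. The topology is taken from the first model and every later
#' model must match it exactly (same atom count, names, residues, order).
#' ATOM and HETATM records are parsed; alternate locations other than
#' blank/'A' are skipped; insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param dt_ps frame interval in ps (metadata; PDB stores no time).
#' @param t0_ps time of first frame in ps.
#' @return a `trajectory`.
#' @export
read_multimodel_pdb <- function(path, dt_ps = 10, t0_ps = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (dt_ps <= 0) stop("dt_ps must be > 0")
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_id <- cumsum(startsWith(lines, "MODEL"))
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("no ATOM/HETATM records in ", path)
  atoms <- parse_atom_lines(lines[atom_idx], atom_idx)
  frame_of <- model_id[atoms$line]
  if (max(model_id) == 0L) frame_of <- rep(1L, nrow(atoms))
  frames <- split(seq_len(nrow(atoms)), frame_of)
  first <- atoms[frames[[1]], , drop = FALSE]
  ident_cols <- c("name", "residue_name", "chain", "residue_seq")
  ident_key <- function(df) do.call(paste, c(df[ident_cols], sep = "\r"))
  key0 <- ident_key(first)
  n_fr <- length(frames)
  coords <- array(NA_real_, dim = c(nrow(first), 3L, n_fr))
  for (m in seq_len(n_fr)) {
    fr <- atoms[frames[[m]], , drop = FALSE]
    if (nrow(fr) != nrow(first) || any(ident_key(fr) != key0)) {
      stop("topology mismatch in model ", m,
           ": atoms differ from model 1 (", nrow(fr), " vs ", nrow(first),
           " atoms)")
    }
    coords[, , m] <- as.matrix(fr[, c("x", "y", "z")])
  }
  topology <- first[, c("serial", ident_cols)]
  rownames(topology) <- NULL
  new_trajectory(topology, coords, dt_ps = dt_ps, t0_ps = t0_ps)
}

format_pdb_atom_name <- function(name) {
  # short names start in column 14 by convention (" NZ ", " CA ")
  ifelse(nchar(name) < 4L, sprintf("%-4s", paste0(" ", name)),
         sprintf("%-4s", name))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-column wwPDB format, one MODEL/ENDMDL block per frame, coordinates
#' to 3 decimals; reading the result back reproduces coordinates within
#' 5e-4 Angstrom and the identical topology (residue numbering verbatim).
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  top <- traj$topology
  name4 <- format_pdb_atom_name(top$name)
  elem <- sprintf("%2s", substr(top$name, 1, 1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , m]
    body <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %s",
      top$serial, name4, top$residue_name, top$chain, top$residue_seq,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, elem)
    writeLines(c(sprintf("MODEL     %4d", m), body, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a distance time-series
#'
#' @param times_ps strictly increasing times in ps.
#' @param values_A distances in Angstrom (>= 0), same length.
#' @param label_a,label_b identifiers of the two charged groups
#'   (e.g. `"E105"`, `"K109"`).
#' @return object of class `distance_series`.
#' @export
new_distance_series <- function(times_ps, values_A, label_a, label_b) {
  if (length(times_ps) != length(values_A)) {
    stop("times and values must have equal length")
  }
  if (length(times_ps) == 0L) stop("empty series")
  if (any(diff(times_ps) <= 0)) stop("times must be strictly increasing")
  if (any(values_A < 0)) stop("distances must be non-negative")
  structure(
    list(times_ps = as.numeric(times_ps), values_A = as.numeric(values_A),
         label_a = as.character(label_a), label_b = as.character(label_b)),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s-%s, %d points, %.1f-%.1f ps\n",
              x$label_a, x$label_b, length(x$times_ps),
              min(x$times_ps), max(x$times_ps)))
  invisible(x)
}

#' Write a distance series as TSV
#'
#' Two `# label_a=` / `# label_b=` metadata lines, then a header
#' `time_ps<TAB>distance_A` and the data at full precision (lossless
#' round-trip to at least 6 significant digits).
#'
#' @param series a `distance_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_series <- function(series, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# label_a=%s", series$label_a),
               sprintf("# label_b=%s", series$label_b),
               "time_ps\tdistance_A"), con)
  writeLines(sprintf("%.17g\t%.17g", series$times_ps, series$values_A), con)
  invisible(path)
}

#' Read a distance series from TSV
#'
#' @param path file written by [write_distance_series()] (or any TSV with
#'   `time_ps` and `distance_A` columns and optional `# key=value` headers).
#' @return a `distance_series`.
#' @export
read_distance_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  for (col in c("time_ps", "distance_A")) {
    if (!col %in% names(tab)) stop("missing required column: ", col)
  }
  if (any(diff(tab$time_ps) <= 0)) stop("times must be strictly increasing")
  new_distance_series(tab$time_ps, tab$distance_A,
                      label_a = meta$label_a %||% "a",
                      label_b = meta$label_b %||% "b")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
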