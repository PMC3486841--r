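# Charged-group definitions: side-chain atoms that carry the formal charge.
# Histidine is included only when the protonation policy says it is charged
# (doubly protonated imidazolium), which is the expected state for
# solvent-exposed histidines at the mildly acidic intracellular pH of yeast.
GROUP_DEFS <- list(
  ASP = list(group_type = "carboxylate",  sign = -1L, atoms = c("OD1", "OD2")),
  GLU = list(group_type = "carboxylate",  sign = -1L, atoms = c("OE1", "OE2")),
  LYS = list(group_type = "ammonium",     sign = +1L, atoms = "NZ"),
  ARG = list(group_type = "guanidinium",  sign = +1L, atoms = c("NE", "NH1", "NH2")),
  HIS = list(group_type = "imidazolium",  sign = +1L, atoms = c("ND1", "NE2"))
)

AA_ONE_LETTER <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Protonation policy for ionizable side chains
#'
#' Controls which residues count as charged. By default histidine is treated
#' as charged (imidazolium) below pH 6, matching the expectation that
#' solvent-exposed histidines are protonated at the mildly acidic pH (~5.5)
#' found in yeast cells.
#'
#' @param pH solution pH in \[0, 14\].
#' @param histidine_charged override the pH-derived histidine state.
#' @return object of class `protonation_policy`.
#' @export
protonation_policy <- function(pH = 5.5, histidine_charged = NULL) {
  if (!is.numeric(pH) || length(pH) != 1L || pH < 0 || pH > 14) {
    stop("pH must be a single value in [0, 14]")
  }
  if (is.null(histidine_charged)) histidine_charged <- pH < 6.0
  structure(list(pH = pH, histidine_charged = isTRUE(histidine_charged)),
            class = "protonation_policy")
}

#' Construct a charged group
#'
#' @param chain chain identifier.
#' @param residue_seq residue number (verbatim from the structure).
#' @param residue_name 3-letter residue code.
#' @param group_type one of carboxylate, ammonium, guanidinium, imidazolium,
#'   n_terminus, c_terminus.
#' @param sign +1 (basic) or -1 (acidic).
#' @param atoms atom names carrying the charge.
#' @return object of class `charged_group` with a display `label` such as
#'   `"K109"` (one-letter code + residue number).
#' @export
charged_group <- function(chain, residue_seq, residue_name, group_type,
                          sign, atoms) {
  stopifnot(sign %in% c(-1L, 1L), length(atoms) >= 1L)
  acidic <- group_type %in% c("carboxylate", "c_terminus")
  if (acidic && sign != -1L) stop("acidic group must have sign -1")
  if (!acidic && sign != 1L) stop("basic group must have sign +1")
  one <- unname(AA_ONE_LETTER[residue_name])
  label <- paste0(if (is.na(one)) residue_name else one, residue_seq)
  structure(
    list(chain = chain, residue_seq = as.integer(residue_seq),
         residue_name = residue_name, group_type = group_type,
         sign = as.integer(sign), atoms = atoms, label = label),
    class = "charged_group"
  )
}

#' @export
print.charged_group <- function(x, ...) {
  cat(sprintf("<charged_group> %s (%s, %s%d) atoms: %s\n", x$label,
              x$group_type, if (x$sign > 0) "+" else "", x$sign,
              paste(x$atoms, collapse = ",")))
  invisible(x)
}

#' Identify ionizable charged groups in a topology
#'
#' One group per ionizable side chain whose charge atoms are present.
#' Histidine is included only if the policy marks it charged; chain termini
#' only if `include_termini` is set. A residue whose charge atoms are all
#' absent is skipped with a warning, never a hard failure. The result is in
#' deterministic (chain, residue number) order.
#'
#' @param topology trajectory topology data.frame (or a `trajectory`).
#' @param policy a [protonation_policy()].
#' @param include_termini also emit N-/C-terminal groups per chain.
#' @return list of `charged_group`.
#' @export
identify_charged_groups <- function(topology, policy = protonation_policy(),
                                    include_termini = FALSE) {
  if (inherits(topology, "trajectory")) topology <- topology$topology
  res <- unique(topology[, c("chain", "residue_seq", "residue_name")])
  res <- res[order(res$chain, res$residue_seq), , drop = FALSE]
  groups <- list()
  for (i in seq_len(nrow(res))) {
    rn <- res$residue_name[i]
    def <- GROUP_DEFS[[rn]]
    if (is.null(def)) next
    if (rn == "HIS" && !policy$histidine_charged) next
    present <- topology$chain == res$chain[i] &
      topology$residue_seq == res$residue_seq[i]
    atoms <- intersect(def$atoms, topology$name[present])
    if (length(atoms) == 0L) {
      warning(sprintf("skipping %s %s%d: charge atoms (%s) absent", rn,
                      res$chain[i], res$residue_seq[i],
                      paste(def$atoms, collapse = ",")), call. = FALSE)
      next
    }
    groups[[length(groups) + 1L]] <- charged_group(
      res$chain[i], res$residue_seq[i], rn, def$group_type, def$sign, atoms)
  }
  if (include_termini) {
    for (ch in unique(res$chain)) {
      in_ch <- res[res$chain == ch, , drop = FALSE]
      first <- in_ch[1L, ]
      last <- in_ch[nrow(in_ch), ]
      n_atoms <- topology$name[topology$chain == ch &
                                 topology$residue_seq == first$residue_seq]
      if ("N" %in% n_atoms) {
        groups[[length(groups) + 1L]] <- charged_group(
          ch, first$residue_seq, first$residue_name, "n_terminus", 1L, "N")
      }
      c_atoms <- intersect(c("O", "OXT"),
                           topology$name[topology$chain == ch &
                                           topology$residue_seq == last$residue_seq])
      if (length(c_atoms) > 0L) {
        groups[[length(groups) + 1L]] <- charged_group(
          ch, last$residue_seq, last$residue_name, "c_terminus", -1L, c_atoms)
      }
    }
  }
  groups
}

group_atom_indices <- function(topology, group) {
  idx <- which(topology$chain == group$chain &
                 topology$residue_seq == group$residue_seq &
                 topology$name %in% group$atoms)
  if (length(idx) == 0L) {
    stop("atoms of group ", group$label, " not found in topology")
  }
  idx
}

#' Minimum inter-group distance in one frame
#'
#' Minimum Euclidean distance over all pairs of charge atoms of the two
#' groups. Like-charge pairs are allowed (useful for probing electrostatic
#' repulsion, e.g. an engineered lysine facing the central lysine) but are
#' never called salt bridges downstream.
#'
#' @param frame a frame from [get_frame()] (list with `topology`, `xyz`).
#' @param group_a,group_b `charged_group`s.
#' @return minimum distance in Angstrom.
#' @export
min_pair_distance <- function(frame, group_a, group_b) {
  ia <- group_atom_indices(frame$topology, group_a)
  ib <- group_atom_indices(frame$topology, group_b)
  xa <- frame$xyz[ia, , drop = FALSE]
  xb <- frame$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

#' Per-frame minimum inter-group distance series
#'
#' Computes the minimum charge-atom distance between two groups for every
#' retained frame. Frames earlier than `exclude_ps` after the trajectory
#' start are dropped — the equilibration convention of discarding the first
#' 1 ns of an MD trajectory before analysis.
#'
#' @param traj a `trajectory`.
#' @param group_a,group_b `charged_group`s.
#' @param exclude_ps initial time span to drop (default 1000 ps = 1 ns).
#' @return a `distance_series` labelled with the group labels.
#' @export
distance_series <- function(traj, group_a, group_b, exclude_ps = 1000) {
  if (exclude_ps < 0) stop("exclude_ps must be >= 0")
  times <- frame_times(traj)
  keep <- times >= traj$t0_ps + exclude_ps
  if (!any(keep)) {
    stop("no frames left after excluding the first ", exclude_ps, " ps")
  }
  ia <- group_atom_indices(traj$topology, group_a)
  ib <- group_atom_indices(traj$topology, group_b)
  kept <- which(keep)
  nk <- length(kept)
  dmin <- rep(Inf, nk)
  for (i in ia) {
    xi <- matrix(traj$coords[i, , kept], nrow = 3L)
    for (j in ib) {
      xj <- matrix(traj$coords[j, , kept], nrow = 3L)
      dmin <- pmin(dmin, sqrt(colSums((xi - xj)^2)))
    }
  }
  new_distance_series(times[kept], dmin, group_a$label, group_b$label)
}

#' Hysteretic salt-bridge state calling
#'
#' Two-threshold state assignment that suppresses flicker at the boundary:
#' FORMED when the distance drops below `d_on`, BROKEN when it rises above
#' `d_off`, and the previous label held inside the gap. The first frame is
#' FORMED iff its value is below the threshold midpoint. No FORMED-to-BROKEN
#' transition can occur without the series exceeding `d_off`.
#'
#' @param series a `distance_series`.
#' @param d_on formation threshold in Angstrom (default 4.0, the common
#'   minimum N-O salt-bridge criterion).
#' @param d_off breakage threshold in Angstrom (default 6.0); must exceed
#'   `d_on`.
#' @return object of class `bridge_state_series` with per-frame labels
#'   `"FORMED"`/`"BROKEN"`.
#' @export
bridge_state_series <- function(series, d_on = 4.0, d_off = 6.0) {
  if (!(d_on < d_off)) stop("d_on must be < d_off")
  v <- series$values_A
  if (length(v) == 0L) stop("empty series")
  state <- ifelse(v < d_on, 1L, ifelse(v > d_off, 0L, NA_integer_))
  if (is.na(state[1L])) state[1L] <- as.integer(v[1L] < (d_on + d_off) / 2)
  known <- !is.na(state)
  state <- state[which(known)][cumsum(known)]  # carry last known label forward
  structure(
    list(times_ps = series$times_ps,
         labels = ifelse(state == 1L, "FORMED", "BROKEN"),
         d_on = d_on, d_off = d_off,
         label_a = series$label_a, label_b = series$label_b),
    class = "bridge_state_series"
  )
}

#' @export
print.bridge_state_series <- function(x, ...) {
  cat(sprintf("<bridge_state_series> %s-%s, %d frames, FORMED %.1f%% (d_on=%g, d_off=%g)\n",
              x$label_a, x$label_b, length(x$labels),
              100 * mean(x$labels == "FORMED"), x$d_on, x$d_off))
  invisible(x)
}
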