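#' Build the time-resolved salt-bridge network
#'
#' Nodes are charged groups; an edge joins every opposite-sign pair whose
#' FORMED occupancy (fraction of retained frames below the hysteretic
#' thresholds) reaches `min_occupancy`. Distance series for each candidate
#' pair are cached on the network so motif detection can reuse them.
#'
#' @param traj a `trajectory`.
#' @param groups list of `charged_group` (e.g. from
#'   [identify_charged_groups()]).
#' @param d_on,d_off hysteretic thresholds in Angstrom (see
#'   [bridge_state_series()]).
#' @param min_occupancy minimum FORMED fraction for an edge (default 0.05;
#'   the boundary is inclusive).
#' @param exclude_ps initial equilibration span to drop in ps.
#' @return object of class `salt_bridge_network` with an `edges` data.frame
#'   (`group_a`, `group_b`, `occupancy`, `mean_distance_A`).
#' @export
build_bridge_network <- function(traj, groups, d_on = 4.0, d_off = 6.0,
                                 min_occupancy = 0.05, exclude_ps = 0) {
  ord <- order(vapply(groups, function(g) g$chain, ""),
               vapply(groups, function(g) g$residue_seq, 0L))
  groups <- groups[ord]
  labels <- vapply(groups, function(g) g$label, "")
  signs <- vapply(groups, function(g) g$sign, 0L)
  edges <- data.frame(group_a = character(), group_b = character(),
                      occupancy = numeric(), mean_distance_A = numeric(),
                      stringsAsFactors = FALSE)
  series_cache <- list()
  n_used <- NA_integer_
  if (length(groups) == 0L) {
    message("no charged groups: returning empty network")
  } else if (length(groups) >= 2L) {
    pairs <- utils::combn(length(groups), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]
      j <- pairs[2L, k]
      if (signs[i] * signs[j] != -1L) next
      ds <- distance_series(traj, groups[[i]], groups[[j]],
                            exclude_ps = exclude_ps)
      n_used <- length(ds$values_A)
      series_cache[[paste(labels[i], labels[j], sep = "|")]] <- ds
      bs <- bridge_state_series(ds, d_on = d_on, d_off = d_off)
      occ <- mean(bs$labels == "FORMED")
      if (occ >= min_occupancy) {
        edges[nrow(edges) + 1L, ] <- list(labels[i], labels[j], occ,
                                          mean(ds$values_A))
      }
    }
  }
  structure(
    list(nodes = groups, edges = edges, n_frames_used = n_used,
         d_on = d_on, d_off = d_off, exclude_ps = exclude_ps,
         series = series_cache),
    class = "salt_bridge_network"
  )
}

#' @export
print.salt_bridge_network <- function(x, ...) {
  cat(sprintf("<salt_bridge_network> %d charged groups, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) print(x$edges)
  invisible(x)
}

#' Retrieve a cached distance series from a salt-bridge network
#'
#' @param network a `salt_bridge_network`.
#' @param label_a,label_b group labels in either order.
#' @return the cached `distance_series`, or NULL if the pair was never a
#'   candidate (same-sign pair or absent group).
#' @export
network_series <- function(network, label_a, label_b) {
  network$series[[paste(label_a, label_b, sep = "|")]] %||%
    network$series[[paste(label_b, label_a, sep = "|")]]
}

#' Detect shuttle motifs in a salt-bridge network
#'
#' A shuttle motif is a central basic group bonded alternately to two
#' distinct acidic partners: the two central-partner distance series are
#' strongly anticorrelated because binding is mutually exclusive. For every
#' basic node with at least two acidic edges, every partner pair whose
#' Pearson rho is at most `rho_max` is emitted, sorted by ascending rho
#' (strongest anticorrelation first). Which partner is the "interface" one
#' cannot be inferred from geometry alone; pass `interface_residues`
#' (labels such as `"E105"`) to assign roles, otherwise partners are left
#' unassigned in network order.
#'
#' @param network a `salt_bridge_network` (built from `traj`).
#' @param traj the same `trajectory` the network was built from (used to
#'   recompute any distance series missing from the cache).
#' @param rho_max anticorrelation screening threshold (default -0.5).
#' @param interface_residues optional character vector of interface acidic
#'   group labels.
#' @return list of `shuttle_motif` objects with fields `central`,
#'   `interface_partner`, `remote_partner` (or unassigned `partner_a`/`_b`),
#'   and `rho`.
#' @export
detect_shuttle_motifs <- function(network, traj, rho_max = -0.5,
                                  interface_residues = NULL) {
  groups <- network$nodes
  labels <- vapply(groups, function(g) g$label, "")
  motifs <- list()
  for (ci in which(vapply(groups, function(g) g$sign, 0L) == 1L)) {
    central <- groups[[ci]]
    on_edge <- network$edges$group_a == central$label |
      network$edges$group_b == central$label
    partners <- setdiff(unique(c(network$edges$group_a[on_edge],
                                 network$edges$group_b[on_edge])),
                        central$label)
    partners <- partners[vapply(partners, function(p)
      groups[[match(p, labels)]]$sign == -1L, TRUE)]
    if (length(partners) < 2L) next
    for (pp in utils::combn(partners, 2L, simplify = FALSE)) {
      s1 <- network_series(network, central$label, pp[1]) %||%
        distance_series(traj, central, groups[[match(pp[1], labels)]],
                        exclude_ps = network$exclude_ps)
      s2 <- network_series(network, central$label, pp[2]) %||%
        distance_series(traj, central, groups[[match(pp[2], labels)]],
                        exclude_ps = network$exclude_ps)
      rho <- anticorrelation(s1, s2)$rho
      if (rho <= rho_max) {
        motifs[[length(motifs) + 1L]] <- new_shuttle_motif(
          central, groups[[match(pp[1], labels)]],
          groups[[match(pp[2], labels)]], rho, interface_residues)
      }
    }
  }
  motifs[order(vapply(motifs, function(m) m$rho, 0))]
}

new_shuttle_motif <- function(central, partner_a, partner_b, rho,
                              interface_residues = NULL) {
  stopifnot(central$sign == 1L, partner_a$sign == -1L, partner_b$sign == -1L)
  if (identical(partner_a$label, partner_b$label)) {
    stop("shuttle partners must be distinct")
  }
  interface <- NULL
  remote <- NULL
  if (!is.null(interface_residues)) {
    a_if <- partner_a$label %in% interface_residues
    b_if <- partner_b$label %in% interface_residues
    if (a_if && !b_if) { interface <- partner_a; remote <- partner_b }
    if (b_if && !a_if) { interface <- partner_b; remote <- partner_a }
  }
  structure(
    list(central = central, partner_a = partner_a, partner_b = partner_b,
         interface_partner = interface, remote_partner = remote, rho = rho),
    class = "shuttle_motif"
  )
}

#' @export
print.shuttle_motif <- function(x, ...) {
  roles <- if (!is.null(x$interface_partner)) {
    sprintf("interface %s / remote %s", x$interface_partner$label,
            x$remote_partner$label)
  } else {
    sprintf("partners %s / %s (roles unassigned)", x$partner_a$label,
            x$partner_b$label)
  }
  cat(sprintf("<shuttle_motif> central %s, %s, rho = %.3f\n",
              x$central$label, roles, x$rho))
  invisible(x)
}

#' Classify open/bridged shuttle states
#'
#' Combines the interface and remote bridge-state series frame by frame:
#' interface FORMED with remote BROKEN is BRIDGED (the central residue
#' sequesters the interface acid, binding-impaired); remote FORMED with
#' interface BROKEN is OPEN (interface acid free, binding-competent); both
#' FORMED is BIFURCATED; both BROKEN is UNBOUND.
#'
#' @param b_interface,b_remote `bridge_state_series` on the same time axis.
#' @return object of class `shuttle_state_series`.
#' @export
classify_shuttle_states <- function(b_interface, b_remote) {
  if (length(b_interface$labels) != length(b_remote$labels) ||
      any(b_interface$times_ps != b_remote$times_ps)) {
    stop("time-axis mismatch between interface and remote bridge series")
  }
  fi <- b_interface$labels == "FORMED"
  fr <- b_remote$labels == "FORMED"
  labels <- ifelse(fi & fr, "BIFURCATED",
                   ifelse(fi, "BRIDGED", ifelse(fr, "OPEN", "UNBOUND")))
  structure(list(times_ps = b_interface$times_ps, labels = labels),
            class = "shuttle_state_series")
}

#' @export
print.shuttle_state_series <- function(x, ...) {
  tab <- table(factor(x$labels, levels = SHUTTLE_STATES))
  cat("<shuttle_state_series>", length(x$labels), "frames:",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / length(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

SHUTTLE_STATES <- c("OPEN", "BRIDGED", "BIFURCATED", "UNBOUND")

#' Occupancies and exchange kinetics of a shuttle
#'
#' State occupancies (fractions over all frames, summing to 1), the number
#' of OPEN/BRIDGED interconversions, the exchange rate per ns, and dwell
#' statistics per state. Exchange counting is gap-tolerant: BIFURCATED or
#' UNBOUND frames between an OPEN and a BRIDGED visit do not reset the
#' transition, since exchanges proceed through transient intermediates.
#'
#' @param states a `shuttle_state_series` with >= 2 frames.
#' @param rho optional anticorrelation to carry into the result (from the
#'   motif).
#' @return object of class `shuttle_stats`.
#' @export
shuttle_kinetics <- function(states, rho = NULL) {
  labels <- states$labels
  n <- length(labels)
  if (n < 2L) stop("insufficient data: need at least 2 frames")
  dt <- stats::median(diff(states$times_ps))
  occupancy <- as.numeric(table(factor(labels, levels = SHUTTLE_STATES))) / n
  names(occupancy) <- SHUTTLE_STATES
  core <- labels[labels %in% c("OPEN", "BRIDGED")]
  n_exchanges <- if (length(core) > 1L) sum(core[-1L] != core[-length(core)])
  else 0L
  duration_ns <- n * dt / 1000
  runs <- rle(labels)
  dwell <- lapply(stats::setNames(SHUTTLE_STATES, SHUTTLE_STATES),
                  function(s) {
                    len <- runs$lengths[runs$values == s] * dt
                    list(n = length(len),
                         mean_ps = if (length(len)) mean(len) else NA_real_,
                         median_ps = if (length(len)) stats::median(len)
                         else NA_real_)
                  })
  structure(
    list(occupancy = occupancy, n_exchanges = as.integer(n_exchanges),
         exchange_rate_per_ns = n_exchanges / duration_ns,
         duration_ns = duration_ns, dwell = dwell, rho = rho),
    class = "shuttle_stats"
  )
}

#' @export
print.shuttle_stats <- function(x, ...) {
  cat("<shuttle_stats>\n  occupancy:",
      paste(sprintf("%s %.3f", names(x$occupancy), x$occupancy),
            collapse = ", "),
      sprintf("\n  exchanges: %d over %.1f ns (%.3f /ns)\n",
              x$n_exchanges, x$duration_ns, x$exchange_rate_per_ns))
  for (s in names(x$dwell)) {
    d <- x$dwell[[s]]
    if (d$n > 0L) cat(sprintf("  dwell %s: n=%d mean=%.0f ps median=%.0f ps\n",
                              s, d$n, d$mean_ps, d$median_ps))
  }
  if (!is.null(x$rho)) cat(sprintf("  rho = %.3f\n", x$rho))
  invisible(x)
}
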