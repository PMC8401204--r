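#' Region ids excluded by the packaged replicate (intrasample) QC list
#' @export
INTRASAMPLE_EXCLUDED <- c(1L, 9L, 21L, 22L, 24L, 27L, 29L, 30L, 31L)

#' Region ids excluded by the packaged cohort (intersample) QC list
#' @export
INTERSAMPLE_EXCLUDED <- c(80L, 209L, 215L, 216L, 217L, 218L, 237L)

#' Configuration for region-table construction
#'
#' @param pad_ppm padding added on each side of a multiplet envelope.
#' @param m_width_hz envelope width assumed for unresolved (`m`) multiplets.
#' @param min_width_ppm smallest admissible region width after overlap
#'   resolution.
#' @param anchor_margin_ppm clearance kept between a region boundary and a
#'   protected line/centre position.
#' @param water_window ppm pair (low, high); no region may intersect it.
#' @param ma_window ppm pair used to integrate the maleic-acid standard;
#'   deliberately outside all 237 regions.
#' @param freq_mhz spectrometer frequency used for Hz-to-ppm conversion.
#' @return a `region_build_config` list.
#' @export
region_build_config <- function(pad_ppm = 0.005, m_width_hz = 12,
                                min_width_ppm = 0.002,
                                anchor_margin_ppm = 0.002,
                                water_window = c(4.7, 4.9),
                                ma_window = c(5.98, 6.04),
                                freq_mhz = 600) {
  stopifnot(pad_ppm >= 0, m_width_hz > 0, min_width_ppm > 0,
            length(water_window) == 2, water_window[1] < water_window[2])
  structure(list(pad_ppm = pad_ppm, m_width_hz = m_width_hz,
                 min_width_ppm = min_width_ppm,
                 anchor_margin_ppm = anchor_margin_ppm,
                 water_window = water_window, ma_window = ma_window,
                 freq_mhz = freq_mhz),
            class = "region_build_config")
}

#' Build the 237-region integration table from the spin library
#'
#' Reconstructs fixed integration windows from the multiplet centres and J
#' couplings of the spin library.  Each proton group claims an envelope of
#' centre +/- (half the expanded multiplet width in ppm) plus padding; a
#' group assigned to k regions has the envelope split into k equal slices
#' (ascending region id following descending ppm).  Line positions of
#' groups that own a single region, and the multiplet centre of every
#' multi-region group (which by symmetry falls in the middle slice), are
#' *protected*: overlap resolution trims padding and outer envelope first
#' and never moves a boundary across a protected position.  Region ids
#' never referenced by the library become filler windows (lipid /
#' non-identified territory) tiling the gaps between their assigned
#' neighbours, skipping the water window.
#'
#' @param library a [load_spin_library()] object.
#' @param config a [region_build_config()].
#' @return a `region_table` data frame with columns `var_id`, `ppm_start`
#'   (downfield bound, larger ppm), `ppm_end`, `metabolites` (semicolon
#'   separated, empty for fillers) and `qc_class`.  Regions are half-open
#'   `[ppm_end, ppm_start)` and non-overlapping; ppm descends as `var_id`
#'   ascends.
#' @export
build_region_table <- function(library, config = region_build_config()) {
  cfg <- config
  n_reg <- 237L
  pad <- cfg$pad_ppm
  minw <- cfg$min_width_ppm
  marg <- cfg$anchor_margin_ppm

  hull_lo <- rep(NA_real_, n_reg)
  hull_hi <- rep(NA_real_, n_reg)
  prot <- vector("list", n_reg)    # protected ppm positions per region
  ctrs <- vector("list", n_reg)    # multiplet centres only (fallback)
  members <- vector("list", n_reg)

  for (i in seq_len(nrow(library))) {
    hw <- envelope_halfwidth_hz(library$multiplicity[i], library$j_hz[[i]],
                                cfg$m_width_hz) / cfg$freq_mhz
    ctr <- library$shift_ppm[i]
    lo <- ctr - hw - pad
    hi <- ctr + hw + pad
    v <- sort(library$vars[[i]])
    k <- length(v)
    w <- (hi - lo) / k
    for (r in seq_len(k)) {
      id <- v[r]
      s_lo <- hi - r * w
      s_hi <- hi - (r - 1) * w
      hull_lo[id] <- min(hull_lo[id], s_lo, na.rm = TRUE)
      hull_hi[id] <- max(hull_hi[id], s_hi, na.rm = TRUE)
      members[[id]] <- union(members[[id]], library$metabolite[i])
    }
    if (k == 1L) {
      # protect every line of a single-region multiplet
      if (library$multiplicity[i] %in% c("s", "m")) lines <- ctr
      else lines <- ctr + multiplet_pattern(library$multiplicity[i],
                                            library$j_hz[[i]],
                                            1)$offset_hz / cfg$freq_mhz
      prot[[v]] <- c(prot[[v]], lines)
      ctrs[[v]] <- c(ctrs[[v]], ctr)
    }
    # multi-region groups impose no hard constraint: their envelope is
    # shared out among the claimed regions and coverage is judged on the
    # span of those regions
  }

  assigned <- which(!is.na(hull_hi))
  wlo <- cfg$water_window[1]
  whi <- cfg$water_window[2]

  # anchors: the stretch of each region that cannot be traded away
  a_lo <- rep(NA_real_, n_reg)
  a_hi <- rep(NA_real_, n_reg)
  p_min <- rep(NA_real_, n_reg)
  p_max <- rep(NA_real_, n_reg)
  for (id in assigned) {
    if (length(prot[[id]])) {
      if (any(prot[[id]] > wlo & prot[[id]] < whi))
        stop("protected line of VAR ", id, " falls inside the water window")
      p_min[id] <- min(prot[[id]])
      p_max[id] <- max(prot[[id]])
    } else {
      ctr <- (hull_lo[id] + hull_hi[id]) / 2
      p_min[id] <- p_max[id] <- ctr
    }
    a_lo[id] <- p_min[id] - marg
    a_hi[id] <- p_max[id] + marg
  }

  # keep hulls and anchors clear of the water window
  for (id in assigned) {
    if (hull_lo[id] < whi && hull_hi[id] > wlo) {
      if ((p_min[id] + p_max[id]) / 2 > (wlo + whi) / 2) {
        hull_lo[id] <- max(hull_lo[id], whi)
        a_lo[id] <- max(a_lo[id], whi)
      } else {
        hull_hi[id] <- min(hull_hi[id], wlo)
        a_hi[id] <- min(a_hi[id], wlo)
      }
    }
  }

  # resolve anchor collisions between successive assigned regions; regions
  # without genuinely protected lines (pseudo anchors) yield first
  has_pts <- vapply(prot, function(p) length(p) > 0, logical(1))
  eps <- 1e-4
  for (j in seq_len(length(assigned) - 1L)) {
    i <- assigned[j]       # downfield (higher ppm, lower id)
    k <- assigned[j + 1L]  # upfield
    m <- k - i - 1L        # fillers in between
    need <- m * minw
    if (a_hi[k] + need <= a_lo[i]) next
    if (has_pts[i] && has_pts[k]) {
      if (p_max[k] + eps > p_min[i] - eps) {
        # outer lines of crowded multiplets interleave: fall back to
        # protecting only the multiplet centres on both sides
        p_min[i] <- min(ctrs[[i]]); p_max[i] <- max(ctrs[[i]])
        p_min[k] <- min(ctrs[[k]]); p_max[k] <- max(ctrs[[k]])
        a_lo[i] <- max(a_lo[i], p_min[i] - marg)
        a_hi[k] <- min(a_hi[k], p_max[k] + marg)
        if (a_hi[k] + need <= a_lo[i]) next
      }
      if (p_max[k] + eps > p_min[i] - eps) {
        # irreducible conflict between neighbouring centres: split the
        # anchor overlap at its midpoint; coverage of the affected centres
        # is then judged against the span of all their assigned regions
        b <- (a_lo[i] + a_hi[k]) / 2
        a_lo[i] <- b + need / 2
        a_hi[i] <- max(a_hi[i], a_lo[i] + minw)
        a_hi[k] <- b - need / 2
        a_lo[k] <- min(a_lo[k], a_hi[k] - minw)
        next
      }
      b <- (p_min[i] + p_max[k]) / 2
      b <- min(max(b, p_max[k] + eps), p_min[i] - eps)
      half <- min(need / 2, (p_min[i] - p_max[k]) / 2 - eps)
      a_lo[i] <- b + half
      a_hi[k] <- b - half
    } else if (has_pts[i]) {
      a_hi[k] <- a_lo[i] - need
      a_lo[k] <- min(a_lo[k], a_hi[k] - minw)
    } else if (has_pts[k]) {
      a_lo[i] <- a_hi[k] + need
      a_hi[i] <- max(a_hi[i], a_lo[i] + minw)
    } else {
      b <- (a_lo[i] + a_hi[k]) / 2
      a_lo[i] <- b + need / 2
      a_hi[i] <- max(a_hi[i], a_lo[i] + minw)
      a_hi[k] <- b - need / 2
      a_lo[k] <- min(a_lo[k], a_hi[k] - minw)
    }
  }

  lo <- a_lo
  hi <- a_hi

  # grow regions back toward their envelope hulls where space allows,
  # keeping room for sandwiched fillers
  for (j in seq_len(length(assigned) - 1L)) {
    i <- assigned[j]
    k <- assigned[j + 1L]
    m <- k - i - 1L
    band <- lo[i] - hi[k]
    free <- band - m * minw
    if (free <= 0) next
    want_i <- max(lo[i] - hull_lo[i], 0)
    want_k <- max(hull_hi[k] - hi[k], 0)
    tot <- want_i + want_k
    if (tot > free) {
      want_i <- free * want_i / tot
      want_k <- free * want_k / tot
    }
    lo[i] <- lo[i] - want_i
    hi[k] <- hi[k] + want_k
  }
  first <- assigned[1L]
  last <- assigned[length(assigned)]
  hi[first] <- hull_hi[first]
  lo[last] <- hull_lo[last]

  # final monotone sweep: later (upfield) regions never reach above the
  # settled lower edge of their predecessor
  cursor <- Inf
  for (j in seq_along(assigned)) {
    id <- assigned[j]
    m_above <- if (j > 1L) id - assigned[j - 1L] - 1L else 0L
    hi[id] <- min(hi[id], cursor - m_above * minw)
    if (lo[id] > hi[id] - minw) lo[id] <- hi[id] - minw
    cursor <- lo[id]
  }

  # fillers tile the leftover gaps, skipping the water window
  for (j in seq_len(length(assigned) - 1L)) {
    i <- assigned[j]
    k <- assigned[j + 1L]
    m <- k - i - 1L
    if (m == 0L) next
    ids <- seq.int(i + 1L, k - 1L)
    g_lo <- hi[k]
    g_hi <- lo[i]
    subs <- list(c(g_lo, g_hi))
    if (g_lo < whi && g_hi > wlo) {
      subs <- list()
      if (g_hi > whi) subs <- c(subs, list(c(max(g_lo, whi), g_hi)))
      if (g_lo < wlo) subs <- c(subs, list(c(g_lo, min(g_hi, wlo))))
    }
    widths <- vapply(subs, function(s) max(s[2] - s[1], 0), numeric(1))
    if (sum(widths) <= 0)
      stop("no room for filler regions between VAR ", i, " and VAR ", k)
    alloc <- pmax(round(m * widths / sum(widths)), as.integer(widths > 0))
    while (sum(alloc) > m) {
      h <- which.max(alloc)
      alloc[h] <- alloc[h] - 1L
    }
    while (sum(alloc) < m) {
      h <- which.max(widths / pmax(alloc, 1L))
      alloc[h] <- alloc[h] + 1L
    }
    done <- 0L
    for (s in seq_along(subs)) {
      if (alloc[s] == 0L) next
      edges <- seq(subs[[s]][2], subs[[s]][1], length.out = alloc[s] + 1L)
      for (r in seq_len(alloc[s])) {
        id <- ids[done + r]
        hi[id] <- edges[r]
        lo[id] <- edges[r + 1L]
      }
      done <- done + alloc[s]
    }
  }

  qc <- rep("normal", n_reg)
  qc[INTRASAMPLE_EXCLUDED] <- "intrasample_excluded"
  qc[INTERSAMPLE_EXCLUDED] <- "intersample_excluded"

  tab <- data.frame(
    var_id = seq_len(n_reg),
    ppm_start = hi,
    ppm_end = lo,
    metabolites = vapply(members, function(m)
      if (is.null(m)) "" else paste(sort(m), collapse = ";"), character(1)),
    qc_class = qc,
    stringsAsFactors = FALSE
  )
  validate_region_table(tab, library, cfg)
  class(tab) <- c("region_table", "data.frame")
  attr(tab, "water_window") <- cfg$water_window
  attr(tab, "ma_window") <- cfg$ma_window
  tab
}

#' @noRd
validate_region_table <- function(tab, library = NULL,
                                  cfg = region_build_config()) {
  if (nrow(tab) != 237L) stop("region table must have 237 rows, has ",
                              nrow(tab))
  if (!identical(sort(tab$var_id), 1:237))
    stop("region ids must be exactly 1..237")
  if (any(tab$ppm_start <= tab$ppm_end))
    stop("regions with non-positive width: ",
         paste(tab$var_id[tab$ppm_start <= tab$ppm_end], collapse = ", "))
  o <- order(tab$var_id)
  s <- tab$ppm_start[o]
  e <- tab$ppm_end[o]
  bad <- which(s[-1] > e[-length(e)] + 1e-9)
  if (length(bad))
    stop("overlapping regions at VAR ",
         paste(paste(o[bad], o[bad + 1], sep = "/"), collapse = ", "))
  w <- cfg$water_window
  if (any(e < w[2] & s > w[1]))
    stop("regions intersect the water window: ",
         paste(tab$var_id[e < w[2] & s > w[1]], collapse = ", "))
  if (!is.null(library)) {
    tol <- 0.003
    for (i in seq_len(nrow(library))) {
      v <- library$vars[[i]]
      centre <- library$shift_ppm[i]
      # within the ppm span of the group's assigned regions (the regions
      # are contiguous up to interloping neighbours in crowded segments)
      covered <- centre >= min(tab$ppm_end[v]) - tol &&
        centre < max(tab$ppm_start[v]) + tol
      if (!covered)
        stop("multiplet centre of ", library$metabolite[i], " / ",
             library$group[i], " (", centre,
             " ppm) not covered by its assigned regions")
    }
  }
  invisible(tab)
}

#' @export
print.region_table <- function(x, ...) {
  filler <- sum(!nzchar(x$metabolites))
  cat("Region table: 237 fixed integration windows,",
      237 - filler, "metabolite-assigned,", filler, "filler\n")
  cat(sprintf("ppm span: %.3f to %.3f; water window %s; MA window %s\n",
              max(x$ppm_start), min(x$ppm_end),
              paste(attr(x, "water_window"), collapse = "-"),
              paste(attr(x, "ma_window"), collapse = "-")))
  invisible(x)
}

#' Write / read a region table as TSV
#' @param tab a `region_table`.
#' @param path file path.
#' @export
write_region_table <- function(tab, path) {
  out <- as.data.frame(tab)
  attr_line <- sprintf("# water_window=%s ma_window=%s",
                       paste(attr(tab, "water_window"), collapse = ","),
                       paste(attr(tab, "ma_window"), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  out$ppm_start <- format(out$ppm_start, digits = 15, trim = TRUE,
                          scientific = FALSE)
  out$ppm_end <- format(out$ppm_end, digits = 15, trim = TRUE,
                        scientific = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  first <- readLines(path, n = 1L)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$metabolites[is.na(tab$metabolites)] <- ""
  class(tab) <- c("region_table", "data.frame")
  m <- regmatches(first, regexec(
    "water_window=([0-9.]+),([0-9.]+) ma_window=([0-9.]+),([0-9.]+)",
    first))[[1]]
  if (length(m) == 5) {
    attr(tab, "water_window") <- as.numeric(m[2:3])
    attr(tab, "ma_window") <- as.numeric(m[4:5])
  }
  validate_region_table(tab)
  tab
}

#' Region ids whose annotation includes a metabolite
#' @param tab a `region_table`.
#' @param metabolite metabolite name.
#' @return integer vector of var ids.
#' @export
regions_for <- function(tab, metabolite) {
  hit <- vapply(strsplit(tab$metabolites, ";", fixed = TRUE),
                function(m) metabolite %in% m, logical(1))
  tab$var_id[hit]
}
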