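#' Select the loading step closest to a target reaction force
#'
#' Model variants are compared at the loading step whose reaction force is
#' closest to the target (0.3 N); ties go to the earlier step.
#'
#' @param history data.frame from [reaction_history()] (or numeric vector).
#' @param target target force, N.
#' @return the selected step id.
#' @export
select_step <- function(history, target = 0.3) {
  if (is.data.frame(history)) {
    f <- history$reaction
    ids <- history$step
  } else {
    f <- as.numeric(history)
    ids <- seq_along(f) - 1L
  }
  if (!length(f)) stop("empty reaction history")
  ids[which.min(abs(f - target))]
}

#' Partition the articular surface into medial and lateral condyles
#'
#' Sagittal plane through the centroid of the femoral articular surface,
#' normal along the medio-lateral (x) axis; lateral is the smaller-x side
#' (matching the phantom convention). Override `split_x` to impose the
#' plane. Errors if either side of the femoral articular surface is empty.
#'
#' @param mesh a `tet_mesh` with `femoral_cartilage_surface` extracted.
#' @param split_x optional plane position, mm.
#' @export
partition_condyles <- function(mesh, split_x = NULL) {
  fs <- mesh$facet_sets$femoral_cartilage_surface
  if (is.null(fs) || nrow(fs) == 0) stop("femoral cartilage surface is empty")
  nodes <- unique(as.integer(fs[, 1:3]))
  xs <- mesh$nodes[nodes, 1]
  if (is.null(split_x)) split_x <- mean(xs)
  lab <- ifelse(xs < split_x, "lateral", "medial")
  if (!any(lab == "lateral") || !any(lab == "medial"))
    stop("condyle partition leaves one side empty")
  structure(list(split_x = split_x, surface_nodes = nodes, labels = lab),
            class = "condyle_partition")
}

#' @export
print.condyle_partition <- function(x, ...) {
  cat(sprintf("<condyle_partition> split at x = %.4g mm (%d lateral / %d medial surface nodes)\n",
              x$split_x, sum(x$labels == "lateral"), sum(x$labels == "medial")))
  invisible(x)
}

condyle_of <- function(partition, x_coords) {
  ifelse(x_coords < partition$split_x, "lateral", "medial")
}

#' Per-condyle contact-pressure summary at one step
#'
#' A node is *contacting* when its contact pressure is positive. Per
#' condyle the summary reports the mean pressure over contacting nodes, the
#' peak pressure excluding isolated points (a contacting node is isolated
#' when it has fewer than `k_neighbors` contacting neighbours within
#' `radius_factor` times the median inter-node spacing of the slave
#' surface), the frequency histogram (bins of `bin_width` MPa from 0), and
#' the contact area as the summed tributary areas of contacting nodes. A
#' condyle with no contact yields zeros and `no_contact = TRUE` (as happens
#' medially for the one-thickness homogeneous cartilage model).
#'
#' @param sol an `fe_solution`.
#' @param mesh the `tet_mesh` it was solved on.
#' @param step stored step id (e.g. from [select_step()]).
#' @param partition a [partition_condyles()] result.
#' @param k_neighbors,radius_factor isolated-point rule parameters.
#' @param bin_width histogram bin width, MPa.
#' @return data.frame (one row per condyle) with attribute `histograms`.
#' @export
pressure_summary <- function(sol, mesh, step, partition,
                             k_neighbors = 3L, radius_factor = 3,
                             bin_width = 0.2) {
  ids <- vapply(sol$steps, function(s) s$step, 1L)
  st <- sol$steps[[match(step, ids)]]
  if (is.null(st)) stop("step not stored in the solution")
  nodes <- integer(); pres <- numeric(); trib <- numeric()
  for (cc in st$contact) {
    nodes <- c(nodes, cc$nodes)
    pres <- c(pres, cc$pressure)
    trib <- c(trib, cc$tributary)
  }
  xyz <- mesh$nodes[nodes, , drop = FALSE]
  side <- condyle_of(partition, xyz[, 1])
  # median nearest-neighbour spacing over the slave surfaces
  med_h <- median_nn_spacing(xyz)
  rad <- radius_factor * med_h

  out <- list(); hists <- list()
  for (cond in c("lateral", "medial")) {
    sel <- side == cond
    p <- pres[sel]
    a <- trib[sel]
    contacting <- p > 0
    if (!any(contacting)) {
      out[[cond]] <- data.frame(condyle = cond, n_contact = 0L,
                                mean_pressure = 0, peak_pressure = 0,
                                contact_area = 0, step = step,
                                reaction = st$reaction, no_contact = TRUE)
      hists[[cond]] <- list(breaks = numeric(), counts = integer())
      next
    }
    pc <- p[contacting]
    xc <- xyz[sel, , drop = FALSE][contacting, , drop = FALSE]
    # isolated-point exclusion for the peak
    nn <- neighbor_counts(xc, rad)
    eligible <- nn >= k_neighbors
    peak <- if (any(eligible)) max(pc[eligible]) else max(pc)
    brk <- seq(0, max(pc) + bin_width, by = bin_width)
    h <- graphics::hist(pc, breaks = brk, plot = FALSE)
    out[[cond]] <- data.frame(condyle = cond, n_contact = sum(contacting),
                              mean_pressure = mean(pc), peak_pressure = peak,
                              contact_area = sum(a[contacting]), step = step,
                              reaction = st$reaction, no_contact = FALSE)
    hists[[cond]] <- list(breaks = h$breaks, counts = h$counts)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "histograms") <- hists
  res
}

median_nn_spacing <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(Inf)
  take <- if (n > 1200) xyz[seq(1, n, length.out = 1200), , drop = FALSE] else xyz
  d <- as.matrix(stats::dist(take))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

neighbor_counts <- function(xyz, radius) {
  n <- nrow(xyz)
  if (n == 1) return(0L)
  if (n <= 4000) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    return(rowSums(d <= radius))
  }
  cnt <- integer(n)
  blk <- 1000L
  for (i0 in seq(1, n, by = blk)) {
    i1 <- min(i0 + blk - 1L, n)
    d <- outer(rowSums(xyz[i0:i1, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[i0:i1, , drop = FALSE] %*% t(xyz)
    cnt[i0:i1] <- rowSums(d <= radius^2) - 1L
  }
  cnt
}

#' Compare model variants at matched reaction force
#'
#' Per-condyle table of mean/peak contact pressure and contact area for
#' every variant, with percent differences relative to a baseline variant
#' (`100 * (x - x_base) / x_base`). By convention the baseline for the
#' lateral condyle is the simplest model (one-thickness homogeneous
#' cartilage) and for the medial condyle the two-thickness model, which is
#' the simplest model showing medial contact. Missing variants are marked
#' absent.
#'
#' @param summaries named list variant -> [pressure_summary()] data.frame.
#' @param baseline named character: baseline variant per condyle.
#' @export
compare_models <- function(summaries,
                           baseline = c(lateral = "generic_one_thickness",
                                        medial = "generic_two_thickness")) {
  rows <- list()
  for (v in names(summaries)) {
    s <- summaries[[v]]
    if (is.null(s)) {
      rows[[v]] <- data.frame(variant = v, condyle = c("lateral", "medial"),
                              absent = TRUE, mean_pressure = NA, peak_pressure = NA,
                              contact_area = NA, reaction = NA, no_contact = NA)
    } else {
      rows[[v]] <- data.frame(variant = v, condyle = s$condyle, absent = FALSE,
                              mean_pressure = s$mean_pressure,
                              peak_pressure = s$peak_pressure,
                              contact_area = s$contact_area,
                              reaction = s$reaction, no_contact = s$no_contact)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pct <- function(x, b) {
    if (length(b) != 1 || is.na(b) || b == 0) return(rep(NA_real_, length(x)))
    100 * (x - b) / b
  }
  tab$pct_mean <- NA_real_
  tab$pct_peak <- NA_real_
  for (cond in unique(tab$condyle)) {
    bvar <- baseline[[cond]]
    if (is.null(bvar) || !(bvar %in% tab$variant)) next
    bi <- which(tab$variant == bvar & tab$condyle == cond)
    sel <- tab$condyle == cond
    tab$pct_mean[sel] <- pct(tab$mean_pressure[sel], tab$mean_pressure[bi])
    tab$pct_peak[sel] <- pct(tab$peak_pressure[sel], tab$peak_pressure[bi])
  }
  tab
}

#' Contact-pressure frequency plot for one or more variants
#'
#' Frequency of contacting nodes per pressure bin, per condyle, in the
#' style of per-condyle frequency plots of cartilage contact pressure.
#'
#' @param hist_list named list variant -> histograms attribute of
#'   [pressure_summary()].
#' @param condyle `"lateral"` or `"medial"`.
#' @param path optional SVG/PNG output path (by extension).
#' @export
plot_pressure_frequency <- function(hist_list, condyle = "lateral", path = NULL) {
  if (!is.null(path)) {
    if (grepl("\\.svg$", path)) grDevices::svg(path, width = 7, height = 5)
    else grDevices::png(path, width = 900, height = 640)
    on.exit(grDevices::dev.off())
  }
  cols <- grDevices::hcl.colors(max(2L, length(hist_list)), "Dark 3")
  xmax <- 0; ymax <- 0
  for (h in hist_list) {
    hh <- h[[condyle]]
    if (length(hh$counts)) {
      xmax <- max(xmax, max(hh$breaks))
      ymax <- max(ymax, max(hh$counts))
    }
  }
  graphics::plot(NA, xlim = c(0, max(xmax, 0.2)), ylim = c(0, max(ymax, 1)),
                 xlab = "contact pressure (MPa)", ylab = "contacting nodes",
                 main = sprintf("%s condyle", condyle))
  i <- 0
  for (v in names(hist_list)) {
    i <- i + 1
    hh <- hist_list[[v]][[condyle]]
    if (!length(hh$counts)) next
    mids <- (hh$breaks[-1] + hh$breaks[-length(hh$breaks)]) / 2
    graphics::lines(mids, hh$counts, type = "b", col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = names(hist_list), col = cols[seq_along(hist_list)],
                   lty = 1, pch = 16, bty = "n")
  invisible(NULL)
}
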