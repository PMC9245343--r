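## Internal finite-volume machinery for the axisymmetric release model.
##
## The domain is a cylinder (radius = geometry$domain_radius, height =
## geometry$domain_height above the electrode plane z = 0) discretised on a
## graded tensor-product (r, z) grid.  Regions, classified by cell centre:
##   GAP   z < gap                                  (aqueous film, D_out)
##   ZONE  membrane band [gap, gap+L] at all radii, plus the space between
##         the band top and the lower sphere surface for r < R_ves; a zone
##         cell is open pore (D_out) where its annulus falls inside the
##         current pore radius, membrane (no flux) otherwise
##   LUMEN inside the vesicle sphere               (D_in)
##   BATH  everything else                          (D_out)
## The sphere itself stays fixed while the aperture opens (the lost
## spherical-cap volume is < 0.8% for radius ratios below 1/3, see
## spherical_cap_fraction()), so only the zone cells change with R_p(t).

REGION_GAP <- 0L
REGION_ZONE <- 1L
REGION_LUMEN <- 2L
REGION_BATH <- 3L

## geometric sequence of cell edges from `from` to `to`, first width h0,
## widths growing by `ratio`, rescaled so the last edge lands exactly on `to`
graded_edges <- function(from, to, h0, ratio) {
  span <- to - from
  if (span <= h0) {
    return(c(from, to))
  }
  n <- max(1L, ceiling(log(span * (ratio - 1) / h0 + 1) / log(ratio)))
  w <- h0 * ratio^(seq_len(n) - 1)
  w <- w * span / sum(w)
  c(from, from + cumsum(w))
}

uniform_edges <- function(from, to, n) seq(from, to, length.out = n + 1)

build_pde_context <- function(geometry, transport, config = sim_config()) {
  R <- geometry$vesicle_radius
  L <- geometry$pore_length
  gap <- geometry$gap
  z_band_top <- gap + L
  z_centre <- z_band_top + R
  h0 <- config$cell_near_pore
  gf <- config$growth_fine
  gc_ <- config$growth_coarse

  ## radial edges: fine geometric grading out to the vesicle radius (cell
  ## size ~ 0.1 r tracks the pore rim at every radius), coarser beyond
  r_edges <- graded_edges(0, min(R, geometry$domain_radius), h0, gf)
  if (geometry$domain_radius > R) {
    h_last <- diff(utils::tail(r_edges, 2))
    r_edges <- c(r_edges, graded_edges(R, geometry$domain_radius, h_last, gc_)[-1])
  }
  ## axial edges: gap film, membrane band, fine-to-coarse through the
  ## lumen, coarse bath above the sphere
  z_edges <- uniform_edges(0, gap, config$gap_cells)
  z_edges <- c(z_edges, uniform_edges(gap, z_band_top, 2L)[-1])
  z_sphere_top <- z_band_top + 2 * R
  z_edges <- c(z_edges, graded_edges(z_band_top, z_sphere_top, h0 * 2, gf)[-1])
  if (geometry$domain_height > z_sphere_top) {
    h_last <- diff(utils::tail(z_edges, 2))
    z_edges <- c(z_edges, graded_edges(z_sphere_top, geometry$domain_height, h_last, gc_)[-1])
  }

  nr <- length(r_edges) - 1L
  nz <- length(z_edges) - 1L
  rc <- (r_edges[-1] + r_edges[-(nr + 1)]) / 2
  zc <- (z_edges[-1] + z_edges[-(nz + 1)]) / 2
  dr <- diff(r_edges)
  dz <- diff(z_edges)
  ring <- pi * (r_edges[-1]^2 - r_edges[-(nr + 1)]^2) # annulus areas

  id <- function(i, j) i + (j - 1L) * nr
  RC <- matrix(rc, nr, nz)
  ZC <- matrix(zc, nr, nz, byrow = TRUE)

  inside <- RC^2 + (ZC - z_centre)^2 < R^2
  lower_surf <- ifelse(RC < R, z_centre - sqrt(pmax(R^2 - RC^2, 0)), -Inf)
  region <- matrix(REGION_BATH, nr, nz)
  region[ZC < gap] <- REGION_GAP
  region[(ZC >= gap & ZC <= z_band_top) | (ZC < lower_surf & ZC > gap)] <- REGION_ZONE
  region[inside] <- REGION_LUMEN
  region <- as.integer(region)

  n <- nr * nz
  V <- as.vector(matrix(ring, nr, nz) * matrix(dz, nr, nz, byrow = TRUE))
  lumen_ids <- which(region == REGION_LUMEN)
  d_of <- function(reg) ifelse(reg == REGION_LUMEN, transport$d_in, transport$d_out)

  ## ---- face tables -------------------------------------------------------
  sa <- sb <- sg <- numeric(0) # static faces: ids + conductance (m^3/s)
  da <- db <- numeric(0) # dynamic faces (touching a zone cell)
  d_base <- numeric(0) # fully-open conductance
  d_axial <- logical(0)
  d_r1 <- d_r2 <- numeric(0) # radial edges of the zone cell annulus
  d_redge <- numeric(0) # face radius (radial faces)
  d_gap_side <- logical(0) # axial face zone|gap (pore mouth plane)
  d_col1_top <- logical(0)
  d_col1_bot <- logical(0)

  add_static <- function(a, b, g) {
    sa[[length(sa) + 1]] <<- a
    sb[[length(sb) + 1]] <<- b
    sg[[length(sg) + 1]] <<- g
  }
  add_dyn <- function(a, b, g, axial, i_zone, redge, gap_side, c1top, c1bot) {
    k <- length(da) + 1
    da[[k]] <<- a
    db[[k]] <<- b
    d_base[[k]] <<- g
    d_axial[[k]] <<- axial
    d_r1[[k]] <<- r_edges[i_zone]
    d_r2[[k]] <<- r_edges[i_zone + 1]
    d_redge[[k]] <<- redge
    d_gap_side[[k]] <<- gap_side
    d_col1_top[[k]] <<- c1top
    d_col1_bot[[k]] <<- c1bot
  }

  for (j in seq_len(nz)) {
    for (i in seq_len(nr)) {
      a <- id(i, j)
      ra <- region[a]
      ## radial face to (i+1, j)
      if (i < nr) {
        b <- id(i + 1L, j)
        rb <- region[b]
        A <- 2 * pi * r_edges[i + 1] * dz[j]
        res <- (dr[i] / 2) / d_of(ra) + (dr[i + 1] / 2) / d_of(rb)
        g <- A / res
        zone_a <- ra == REGION_ZONE
        zone_b <- rb == REGION_ZONE
        if (!zone_a && !zone_b) {
          open <- !xor(ra == REGION_LUMEN, rb == REGION_LUMEN) # membrane blocks
          if (open) add_static(a, b, g)
        } else if (!(REGION_BATH %in% c(ra, rb))) {
          ## zone radial face: open only when the pore covers the face radius
          add_dyn(a, b, g, FALSE, if (zone_a) i else i + 1L,
            redge = r_edges[i + 1], FALSE, FALSE, FALSE
          )
        }
      }
      ## axial face to (i, j+1)
      if (j < nz) {
        b <- id(i, j + 1L)
        rb <- region[b]
        A <- ring[i]
        res <- (dz[j] / 2) / d_of(ra) + (dz[j + 1] / 2) / d_of(rb)
        g <- A / res
        zone_a <- ra == REGION_ZONE
        zone_b <- rb == REGION_ZONE
        if (!zone_a && !zone_b) {
          open <- !xor(ra == REGION_LUMEN, rb == REGION_LUMEN)
          if (open) add_static(a, b, g)
        } else if (!(REGION_BATH %in% c(ra, rb))) {
          i_zone <- i
          gap_side <- (ra == REGION_GAP) || (rb == REGION_GAP)
          lum_side <- (ra == REGION_LUMEN) || (rb == REGION_LUMEN)
          add_dyn(a, b, g, TRUE, i_zone,
            redge = NA_real_,
            gap_side = gap_side,
            c1top = lum_side && i == 1L,
            c1bot = gap_side && i == 1L
          )
        }
      }
    }
  }

  ## electrode: Dirichlet C = 0 over the bottom plane within the disk radius
  dirg <- numeric(n)
  on_disk <- rc <= geometry$electrode_radius
  dirg[id(which(on_disk), 1L)] <- ring[on_disk] * transport$d_out / (dz[1] / 2)

  ctx <- new.env(parent = emptyenv())
  ctx$geometry <- geometry
  ctx$transport <- transport
  ctx$config <- config
  ctx$nr <- nr
  ctx$nz <- nz
  ctx$n <- n
  ctx$V <- V
  ctx$region <- region
  ctx$lumen_ids <- lumen_ids
  ctx$V_lumen <- sum(V[lumen_ids])
  ctx$static <- list(a = as.integer(unlist(sa)), b = as.integer(unlist(sb)), g = unlist(sg))
  ctx$dyn <- list(
    a = as.integer(unlist(da)), b = as.integer(unlist(db)),
    base = unlist(d_base), axial = unlist(d_axial),
    r1 = unlist(d_r1), r2 = unlist(d_r2), redge = unlist(d_redge),
    gap_side = unlist(d_gap_side),
    col1_top = unlist(d_col1_top), col1_bot = unlist(d_col1_bot)
  )
  ctx$dirg <- dirg
  ctx$r_blend <- 2 * r_edges[2]
  ctx$cache_rp <- NA_real_
  ctx$cache_dt <- NA_real_
  ctx$cache_fac <- NULL
  ctx
}

## conductances of the dynamic (pore-zone) faces at pore radius r_p
dyn_conductance <- function(ctx, r_p) {
  d <- ctx$dyn
  g <- numeric(length(d$a))
  ax <- d$axial
  phi <- pmin(1, pmax(0, (r_p^2 - d$r1[ax]^2) / (d$r2[ax]^2 - d$r1[ax]^2)))
  g[ax] <- d$base[ax] * phi
  g[!ax] <- d$base[!ax] * (r_p >= d$redge[!ax])
  ## sub-mesh blend: below ~2 fine cells the converging access field cannot
  ## be resolved, so the missing access resistance (both sides of the
  ## channel) is added in series on the innermost open column; it vanishes
  ## continuously at r_p = r_blend and reproduces the quasi-steady
  ## conductance scaling for vanishing pores
  if (r_p < ctx$r_blend && r_p > 0) {
    tr <- ctx$transport
    extra_in <- 1 / (4 * tr$d_in * r_p) - 1 / (4 * tr$d_in * ctx$r_blend)
    extra_out <- 1 / (4 * tr$d_out * r_p) - 1 / (4 * tr$d_out * ctx$r_blend)
    top <- d$col1_top & g > 0
    bot <- d$col1_bot & g > 0
    g[top] <- 1 / (1 / g[top] + extra_in)
    g[bot] <- 1 / (1 / g[bot] + extra_out)
  }
  g
}

## backward-Euler system matrix at pore radius r_p and step dt
assemble_system <- function(ctx, r_p, dt) {
  s <- ctx$static
  d <- ctx$dyn
  gd <- dyn_conductance(ctx, r_p)
  idx <- seq_len(ctx$n)
  ## duplicate triplets are summed by sparseMatrix(): off-diagonals -g,
  ## per-face diagonal contributions +g, plus storage and Dirichlet terms
  ti <- c(s$a, s$b, d$a, d$b, s$a, s$b, d$a, d$b, idx)
  tj <- c(s$b, s$a, d$b, d$a, s$a, s$b, d$a, d$b, idx)
  tx <- c(-s$g, -s$g, -gd, -gd, s$g, s$g, gd, gd, ctx$V / dt + ctx$dirg)
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ctx$n, ctx$n))
  list(M = M, gd = gd)
}

solve_be <- function(ctx, r_p, dt, C) {
  reuse <- isTRUE(abs(ctx$cache_rp - r_p) <= 0) && isTRUE(ctx$cache_dt == dt) &&
    !is.null(ctx$cache_fac)
  if (!reuse) {
    sys <- assemble_system(ctx, r_p, dt)
    Ms <- Matrix::forceSymmetric(sys$M)
    ctx$cache_fac <- Matrix::Cholesky(Ms, LDL = FALSE, perm = TRUE)
    ctx$cache_gd <- sys$gd
    ctx$cache_rp <- r_p
    ctx$cache_dt <- dt
  }
  Cn <- as.numeric(Matrix::solve(ctx$cache_fac, ctx$V / dt * C, system = "A"))
  if (any(!is.finite(Cn))) {
    abort("linear solver produced non-finite concentrations",
      class = "poretrace_numerical_error"
    )
  }
  Cn
}

## current through the pore mouth plane (zone | gap faces): Faraday
## conversion of the surface-integrated normal flux
pore_current <- function(ctx, C) {
  d <- ctx$dyn
  gd <- ctx$cache_gd
  sel <- d$gap_side & d$axial
  ## flow from the zone cell (above) into the gap cell (below)
  hi <- ifelse(ctx$region[d$a[sel]] == REGION_ZONE, d$a[sel], d$b[sel])
  lo <- ifelse(ctx$region[d$a[sel]] == REGION_ZONE, d$b[sel], d$a[sel])
  flow <- sum(gd[sel] * (C[hi] - C[lo])) # mol/s
  ctx$transport$n_electrons * ctx$transport$faraday * flow
}

## advance the field over [t, t + span] with pore radius varying linearly
## from r_from to r_to; returns list(C, I_end, released_frac)
advance_pde <- function(ctx, C, r_from, r_to, span, moles0) {
  dt <- ctx$config$dt
  nsub <- max(1L, round(span / dt))
  dt <- span / nsub
  I_end <- 0
  for (k in seq_len(nsub)) {
    r_k <- r_from + (r_to - r_from) * k / nsub
    C <- solve_be(ctx, r_k, dt, C)
    if (k == nsub) I_end <- pore_current(ctx, C)
  }
  released <- if (moles0 > 0) 1 - sum(C * ctx$V) / moles0 else 0
  list(C = C, I = I_end, released_frac = released)
}
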