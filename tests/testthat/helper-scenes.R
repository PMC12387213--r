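# shared fixture builders; everything is generated in code at test time

# analytic grating whose structure axis lies at `mu_deg` (screen CCW,
# 0 deg = horizontal), period in px
make_grating <- function(mu_deg, h = 128L, w = 128L, period_px = 8) {
  th <- mu_deg * pi / 180
  nx <- -sin(th); ny <- cos(th)           # normal in (x, y-up) coordinates
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- -matrix(seq_len(h), h, w)
  cos(2 * pi * (xs * nx + ys * ny) / period_px)
}

# counterclockwise 90-degree rotation in display orientation
rot_ccw90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# standard clean single-orientation validation scene: frame-spanning fibers
# so the nominal mu is the exact ground truth of the weighted orientation
oriented_scene <- function(mu_deg, seed, kappa = 1e6, size = 256L) {
  cfg <- scene_config(size, size, 0.5, seed = seed)
  spec <- filament_texture_spec(mu_deg = mu_deg, kappa = kappa,
                                spatial_period_um = 10, n_filaments = 120L,
                                length_factor = 40)
  make_filament_texture(cfg, spec)
}

# summary margin excluding the border band where mirror extension reflects
# fiber orientations (wider than the tensor's display margin)
recovery_mask <- function(size = 256L, margin = 16L) {
  m <- matrix(FALSE, size, size)
  m[(margin + 1):(size - margin), (margin + 1):(size - margin)] <- TRUE
  m
}

# two-domain scene: left half mu = 0, right half mu = 45 (both kappa = 50)
two_domain_scene <- function(seed, size = 384L) {
  half <- size %/% 2L
  doms <- list(list(x0 = 1L, x1 = half, y0 = 1L, y1 = size,
                    mu_deg = 0, kappa = 50),
               list(x0 = half + 1L, x1 = size, y0 = 1L, y1 = size,
                    mu_deg = 45, kappa = 50))
  cfg <- scene_config(size, size, 0.5, seed = seed)
  spec <- filament_texture_spec(spatial_period_um = 8, n_filaments = 160L,
                                length_factor = 20, domains = doms)
  make_filament_texture(cfg, spec)
}

# drilled-membrane scene: 25 um pores on a 100 um square pitch under a
# saturated fiber mat (sharp pore/cytoplasm step)
pore_scene_standard <- function(seed, halo_um = 0) {
  cfg <- scene_config(600L, 600L, 0.5, seed = seed)
  tex <- filament_texture_spec(mu_deg = 0, kappa = 5,
                               spatial_period_um = 16, n_filaments = 300L,
                               length_factor = 10, saturate = TRUE)
  make_pore_scene(cfg, pore_lattice(25, 100, 100, c(300, 300)), tex,
                  depletion_halo_um = halo_um)
}

# distance (px) to the nearest pore pixel, 0 inside pores
pore_distance_px <- function(pore_mask) {
  t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(!pore_mask)))))
}

# brute-force GLCM oracle: direct pair enumeration with explicit loops
glcm_bruteforce <- function(q, levels, d, angle, symmetric = TRUE,
                            normalized = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L))
  m <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
      m[q[r, cc] + 1L, q[r2, c2] + 1L] <- m[q[r, cc] + 1L, q[r2, c2] + 1L] + 1
  }
  if (symmetric) m <- m + t(m)
  if (normalized) m <- m / sum(m)
  m
}

# independent descriptor oracle: naive double loops straight from the
# textbook definitions (kept free of any shared code with the package)
haralick_bruteforce <- function(p) {
  G <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (a in 1:G) { mux <- mux + (a - 1) * px[a]; muy <- muy + (a - 1) * py[a] }
  vx <- 0; vy <- 0
  for (a in 1:G) { vx <- vx + (a - 1 - mux)^2 * px[a]
                   vy <- vy + (a - 1 - muy)^2 * py[a] }
  sdx <- sqrt(vx); sdy <- sqrt(vy)
  xl <- function(v) if (v > 0) log(v) else 0
  asm <- 0; con <- 0; cor0 <- 0; vari <- 0; idm <- 0; ent <- 0; auto <- 0
  dis <- 0; cs <- 0; cp <- 0; invd <- 0; idn <- 0; idmn <- 0; sosi <- 0
  for (a in 1:G) for (b in 1:G) {
    v <- p[a, b]; ia <- a - 1; jb <- b - 1
    asm <- asm + v^2
    con <- con + (ia - jb)^2 * v
    cor0 <- cor0 + ia * jb * v
    vari <- vari + (ia - mux)^2 * v
    idm <- idm + v / (1 + (ia - jb)^2)
    ent <- ent - v * xl(v)
    auto <- auto + ia * jb * v
    dis <- dis + abs(ia - jb) * v
    cs <- cs + (ia + jb - mux - muy)^3 * v
    cp <- cp + (ia + jb - mux - muy)^4 * v
    invd <- invd + v / (1 + abs(ia - jb))
    idn <- idn + v / (1 + abs(ia - jb) / G)
    idmn <- idmn + v / (1 + (ia - jb)^2 / G^2)
    sosi <- sosi + ia^2 * v
  }
  corr <- if (sdx > 0 && sdy > 0) (cor0 - mux * muy) / (sdx * sdy) else 0
  psum <- numeric(2 * G - 1); pdif <- numeric(G)
  for (a in 1:G) for (b in 1:G) {
    psum[a + b - 1] <- psum[a + b - 1] + p[a, b]
    pdif[abs(a - b) + 1] <- pdif[abs(a - b) + 1] + p[a, b]
  }
  sa <- 0; for (k in seq_along(psum)) sa <- sa + (k - 1) * psum[k]
  sv <- 0; for (k in seq_along(psum)) sv <- sv + (k - 1 - sa)^2 * psum[k]
  se <- 0; for (k in seq_along(psum)) se <- se - psum[k] * xl(psum[k])
  da <- 0; for (k in seq_along(pdif)) da <- da + (k - 1) * pdif[k]
  dv <- 0; for (k in seq_along(pdif)) dv <- dv + (k - 1 - da)^2 * pdif[k]
  de <- 0; for (k in seq_along(pdif)) de <- de - pdif[k] * xl(pdif[k])
  hx <- 0; for (a in 1:G) hx <- hx - px[a] * xl(px[a])
  hy <- 0; for (b in 1:G) hy <- hy - py[b] * xl(py[b])
  hxy1 <- 0; hxy2 <- 0
  for (a in 1:G) for (b in 1:G) {
    hxy1 <- hxy1 - p[a, b] * xl(px[a] * py[b])
    hxy2 <- hxy2 - px[a] * py[b] * xl(px[a] * py[b])
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  nzx <- which(px > 0); nzy <- which(py > 0)
  mcc <- 0
  if (length(nzx) >= 2 && length(nzy) >= 2) {
    Q <- matrix(0, length(nzx), length(nzx))
    for (ai in seq_along(nzx)) for (bi in seq_along(nzx)) {
      s <- 0
      for (ki in seq_along(nzy)) {
        k <- nzy[ki]
        s <- s + p[nzx[ai], k] * p[nzx[bi], k] / (px[nzx[ai]] * py[k])
      }
      Q[ai, bi] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2) mcc <- sqrt(max(0, min(ev[2], 1)))
  }
  c(asm, con, corr, vari, idm, sa, sv, se, ent, dv, de, imc1, imc2,
    auto, dis, cs, cp, max(p), invd, idn, idmn, sosi, mcc)
}
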