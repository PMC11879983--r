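# Exact Hessian of y' c(z) (the constraint part of the Lagrangian) for the
# collocation NLP, assembled sparsely.  Multibody and contact-kinematics
# second derivatives come from the generated weighted-Hessian kernels;
# Hill-muscle, activation, contact-law and passive-moment curvature is
# chained analytically.  Backward-Euler rates r = (x2 - x1) * N / T introduce
# the cross terms d2r/dx dT = -/+ 1/(hT) and d2r/dT2 = 2 r / T^2, applied to
# every rate-dependent row through its weighted rate gradient.

.ocp_lag_hess <- function(z, prob, y) {
  N <- prob$N; lay <- prob$layout; nz <- lay$nz
  p <- prob$seg$p; mus <- prob$mus; bw <- prob$bw
  lo <- prob$lceopt; sdyn <- 1 / bw; sact <- prob$scale_act_row
  st <- .ocp_unpack(z, prob)
  Tt <- st$T; h <- Tt / N
  i2 <- 2:(N + 1L); i1 <- 1:N
  Q1 <- st$Q[, i1, drop = FALSE]; Q2 <- st$Q[, i2, drop = FALSE]
  V1 <- st$V[, i1, drop = FALSE]; V2 <- st$V[, i2, drop = FALSE]
  L1 <- st$LCEn[, i1, drop = FALSE] * lo; L2 <- st$LCEn[, i2, drop = FALSE] * lo
  A1 <- st$ACT[, i1, drop = FALSE]; A2 <- st$ACT[, i2, drop = FALSE]
  U2 <- st$U[, i2, drop = FALSE]
  Aq <- (Q2 - Q1) / h; Av <- (V2 - V1) / h
  Alce <- (L2 - L1) / h; Aact <- (A2 - A1) / h

  Y <- matrix(y[seq_len(N * .ROWS_PER_INT)], .ROWS_PER_INT, N)
  ykin <- Y[1:9, , drop = FALSE]
  ydyn <- Y[10:18, , drop = FALSE] * sdyn
  ycon <- Y[19:34, , drop = FALSE]
  yact <- Y[35:50, , drop = FALSE] * sact
  yctc <- Y[51:66, , drop = FALSE]
  yper <- y[N * .ROWS_PER_INT + 1:.NODE_LEN]

  base1 <- (i1 - 1L) * .NODE_LEN; base2 <- i1 * .NODE_LEN

  ii <- vector("list", 256L); jj <- vector("list", 256L); xx <- vector("list", 256L)
  nb <- 0L
  put <- function(i, j, x) {
    nb <<- nb + 1L
    ii[[nb]] <<- i; jj[[nb]] <<- j
    xx[[nb]] <<- rep_len(as.vector(x), length(i))
  }
  # full block (N, nA, nB): rows offA+i of nodeA, cols offB+j of nodeB
  blk <- function(offA, offB, nA, nB, arr, nodeA = 2L, nodeB = 2L, mirror = TRUE) {
    bA <- if (nodeA == 2L) base2 else base1
    bB <- if (nodeB == 2L) base2 else base1
    iv <- offA + rep(rep(1:nA, each = N), nB) + rep(bA, nA * nB)
    jv <- offB + rep(1:nB, each = N * nA) + rep(bB, nA * nB)
    put(iv, jv, arr)
    if (mirror) put(jv, iv, arr)
  }
  # cross column block against T: valmat (nB x N, i fastest)
  Tcol <- function(offB, nB, valmat, nodeB = 2L) {
    bB <- if (nodeB == 2L) base2 else base1
    jv <- offB + rep(1:nB, N) + rep(bB, each = nB)
    put(jv, rep(lay$i_T, length(jv)), valmat)
    put(rep(lay$i_T, length(jv)), jv, valmat)
  }
  TT <- function(val) put(lay$i_T, lay$i_T, val)

  # ---- kinematic rows: linear except the rate-T chain ----
  Tcol(0L, 9L, -ykin / (h * Tt), nodeB = 2L)
  Tcol(0L, 9L, ykin / (h * Tt), nodeB = 1L)
  TT(2 * sum(ykin * Aq) / Tt^2)

  # ---- dynamics rows ----
  mm <- .moments_mech(Q2, V2, L2, mus, include_passive = TRUE, deriv = TRUE)
  fdec <- st$C[.FROW, i2, drop = FALSE] * bw
  cached <- !is.null(prob$cache) && identical(prob$cache$z, z)
  eom <- if (cached) prob$cache$eom else .dyn_eom(Q2, V2, Av, mm$tau, fdec, p)
  wh <- .dyn_eom_whess(Q2, V2, Av, fdec, ydyn, p)
  blk(0L, 0L, 9L, 9L, wh$Hqq, mirror = FALSE)
  blk(0L, 9L, 9L, 9L, wh$Hqv + wh$Hqa / h)
  blk(0L, 9L, 9L, 9L, -wh$Hqa / h, nodeB = 1L)
  blk(9L, 9L, 9L, 9L, wh$Hvv, mirror = FALSE)
  # f decision variables are stored in bodyweights
  HqfB <- wh$Hqf * bw
  ivq <- rep(rep(1:9, each = N), 8L) + rep(base2, 72L)
  jvf <- 66L + rep(.FROW, each = N * 9L) + rep(base2, 72L)
  put(ivq, jvf, HqfB); put(jvf, ivq, HqfB)
  # a = (v2 - v1)/h depends on T
  daT <- -Av / Tt                                    # 9 x N
  HqT <- matrix(0, 9L, N)
  for (i in 1:9) HqT[i, ] <- rowSums(wh$Hqa[, i, ] * t(daT))
  Tcol(0L, 9L, HqT)
  wa <- matrix(0, 9L, N)                             # weighted a-gradient
  for (j in 1:9) wa[j, ] <- rowSums(eom$Ja[, , j] * t(ydyn))
  Tcol(9L, 9L, -wa / (h * Tt), nodeB = 2L)
  Tcol(9L, 9L, wa / (h * Tt), nodeB = 1L)
  TT(2 * sum(wa * Av) / Tt^2)

  # joint-moment chain curvature: tau rows carry weight -ydyn[4:9]
  yd <- -ydyn[4:9, , drop = FALSE]                   # 6 x N, weight on tau_j
  see2 <- .fsee(musculotendon_length(Q2, mus)$lmt - L2, mus$table$slack,
                mus$table$fmax, deriv2 = TRUE)$d2_lse
  wm <- t(mus$D %*% yd) * t(see2)                    # N x 16: wm * F''
  # entries: (q_{3+j}, q_{3+j'}): sum_m wm D[m,j] D[m,j']  -> via Dpair
  Pm <- wm %*% mus$Dpair                             # N x 36
  blk(3L, 3L, 6L, 6L, array(Pm, c(N, 6L, 6L)), mirror = FALSE)
  # (q_{3+j}, lce_n_m): wm * D[m,j] * lo_m
  arr <- vapply(1:6, function(jx) wm * rep(mus$D[, jx] * lo, each = N),
                matrix(0, N, 16L))
  blk(3L, 18L, 6L, 16L, aperm(arr, c(1L, 3L, 2L)))
  # (lce_n_m, lce_n_m): wm * lo_m^2
  dg <- t(wm) * lo^2                                 # 16 x N
  civ <- 18L + rep(1:16, N) + rep(base2, each = 16L)
  put(civ, civ, dg)
  # passive joint-limit curvature (damping is linear)
  pd2 <- yd * .passive_d2(Q2[4:9, , drop = FALSE])   # 6 x N
  qjv <- 3L + rep(1:6, N) + rep(base2, each = 6L)
  put(qjv, qjv, pd2)

  # ---- contraction rows ----
  tb <- mus$table
  lmt <- musculotendon_length(Q2, mus)$lmt
  ln <- L2 / lo; vn <- Alce / (tb$vmax * lo)
  see <- .fsee(lmt - L2, tb$slack, tb$fmax, deriv2 = TRUE)
  pee <- .fpee(ln, tb$fmax, lo, deriv2 = TRUE)
  fl <- .fl(ln, tb$width); fl1 <- .dfl(ln, tb$width) / lo
  fl2 <- .d2fl(ln, tb$width) / lo^2
  fv <- .fv(vn); fv1 <- .dfv(vn) / (tb$vmax * lo); fv2 <- .d2fv(vn) / (tb$vmax * lo)^2
  sfm <- 1 / tb$fmax
  H_al <- -fl1 * fv                                  # act-lce
  H_ar <- -fl * fv1                                  # act-rate
  H_ll <- see$d2_lse * sfm - A2 * fl2 * fv - pee$d2_lce * sfm
  H_lr <- -A2 * fl1 * fv1
  H_lm <- -see$d2_lse * sfm                          # lce-lmt
  H_rr <- -A2 * fl * fv2
  H_mm <- see$d2_lse * sfm
  wr_c <- ycon * ((-A2 * fl * .dfv(vn) - .HILL$beta) / (tb$vmax * lo)) # y * dr/drate
  # local directions per muscle m (columns over k):
  #   act -> act2[m];  lce -> lce_n2[m] (coef lo)
  #   rate -> lce_n2[m] (lo/h), lce_n1[m] (-lo/h), T (-rate/T)
  #   lmt -> q_{3+j} (coef -D[m,j])
  for (m in 1:16) {
    yc <- ycon[m, ]
    colact <- base2 + 34L + m
    collce2 <- base2 + 18L + m; collce1 <- base1 + 18L + m
    jts <- which(mus$D[m, ] != 0)
    dirs <- list(
      act = list(list(colact, 1)),
      lce = list(list(collce2, lo[m])),
      rate = list(list(collce2, lo[m] / h), list(collce1, -lo[m] / h),
                  list(rep(lay$i_T, N), -Alce[m, ] / Tt)),
      lmt = lapply(jts, function(jx) list(base2 + 3L + jx, -mus$D[m, jx])))
    Hloc <- list(
      list("act", "lce", yc * H_al[m, ]),
      list("act", "rate", yc * H_ar[m, ]),
      list("lce", "lce", yc * H_ll[m, ]),
      list("lce", "rate", yc * H_lr[m, ]),
      list("lce", "lmt", yc * H_lm[m, ]),
      list("rate", "rate", yc * H_rr[m, ]),
      list("lmt", "lmt", yc * H_mm[m, ]))
    for (e in Hloc) {
      da <- dirs[[e[[1]]]]; db <- dirs[[e[[2]]]]
      sym <- identical(e[[1]], e[[2]])
      # for sym pairs the double loop already enumerates both orders
      for (ta in da) for (tb2 in db) {
        val <- e[[3]] * ta[[2]] * tb2[[2]]
        put(ta[[1]], tb2[[1]], val)
        if (!sym) put(tb2[[1]], ta[[1]], val)
      }
    }
    # rate second-order chain: d2rate/d lce_n2 dT etc., weighted by y*dr/drate
    w <- wr_c[m, ]
    put(collce2, rep(lay$i_T, N), -w * lo[m] / (h * Tt))
    put(rep(lay$i_T, N), collce2, -w * lo[m] / (h * Tt))
    put(collce1, rep(lay$i_T, N), w * lo[m] / (h * Tt))
    put(rep(lay$i_T, N), collce1, w * lo[m] / (h * Tt))
    TT(2 * sum(w * Alce[m, ]) / Tt^2)
  }

  # ---- activation rows ----
  d <- U2 - A2
  tdiff <- 1 / tb$tau_act - 1 / tb$tau_deact
  t_ <- tanh(.HILL$k_act * d)
  rho1 <- tdiff * 0.5 * .HILL$k_act * (1 - t_^2)
  rho2 <- tdiff * (-.HILL$k_act^2) * t_ * (1 - t_^2)
  phi2 <- yact * (-(2 * rho1 + d * rho2))            # weighted -phi''
  ucols <- 50L + rep(1:16, N) + rep(base2, each = 16L)
  acols2 <- 34L + rep(1:16, N) + rep(base2, each = 16L)
  acols1 <- 34L + rep(1:16, N) + rep(base1, each = 16L)
  put(ucols, ucols, phi2)
  put(acols2, acols2, phi2)
  put(ucols, acols2, -phi2); put(acols2, ucols, -phi2)
  Tcol(34L, 16L, -yact / (h * Tt), nodeB = 2L)
  Tcol(34L, 16L, yact / (h * Tt), nodeB = 1L)
  TT(2 * sum(yact * Aact) / Tt^2)

  # ---- contact rows ----
  ck <- if (cached) prob$cache$ck else .dyn_cpkin(Q2, V2, p)
  cd <- .contact_force_d2(ck$py, ck$vx, ck$vy, prob$contact)
  ypx <- yctc[c(1, 5, 9, 13), , drop = FALSE]
  ypy <- yctc[c(2, 6, 10, 14), , drop = FALSE]
  yfx <- yctc[c(3, 7, 11, 15), , drop = FALSE]
  yfy <- yctc[c(4, 8, 12, 16), , drop = FALSE]
  # first-derivative part through the kinematic curvature
  wpx <- -ypx
  wpy <- -ypy - (yfx * t(cd$fx_py) + yfy * t(cd$fy_py)) / bw
  wvx <- -(yfx * t(cd$fx_vx) + yfy * t(cd$fy_vx)) / bw
  wvy <- -(yfx * t(cd$fx_vy) + yfy * t(cd$fy_vy)) / bw
  cw <- .dyn_cpkin_whess(Q2, V2, wpx, wpy, wvx, wvy, p)
  blk(0L, 0L, 9L, 9L, cw$Hqq, mirror = FALSE)
  blk(0L, 9L, 9L, 9L, cw$Hqv)
  # force-law curvature: sum_ab C_ab * g_a' g_b with g = z-gradient (q, v) of
  # (py, vx, vy); the ordered double sum over the full symmetric C gives the
  # symmetric Hessian directly
  kin3 <- c("py", "vx", "vy")
  for (pt in 1:4) {
    G <- list(py = cbind(ck$Jpy[, pt, ], matrix(0, N, 9L)),
              vx = cbind(ck$Jvx[, pt, ], ck$Jpx[, pt, ]),
              vy = cbind(ck$Jvy[, pt, ], ck$Jpy[, pt, ]))
    cf2 <- function(nm) -(yfx[pt, ] * cd[[paste0("fx_", nm)]][, pt] +
                          yfy[pt, ] * cd[[paste0("fy_", nm)]][, pt]) / bw
    C3 <- matrix(list(), 3, 3, dimnames = list(kin3, kin3))
    C3[["py", "py"]] <- cf2("pypy"); C3[["vx", "vx"]] <- cf2("vxvx")
    C3[["vy", "vy"]] <- cf2("vyvy")
    C3[["py", "vx"]] <- C3[["vx", "py"]] <- cf2("pyvx")
    C3[["py", "vy"]] <- C3[["vy", "py"]] <- cf2("pyvy")
    C3[["vx", "vy"]] <- C3[["vy", "vx"]] <- cf2("vyvx")
    arr <- array(0, c(N, 18L, 18L))
    for (a in kin3) for (b in kin3) {
      coef <- C3[[a, b]]
      if (all(coef == 0)) next
      Ga <- G[[a]]; Gb <- G[[b]]
      for (i in 1:18) if (any(Ga[, i] != 0))
        arr[, i, ] <- arr[, i, ] + (coef * Ga[, i]) * Gb
    }
    blk(0L, 0L, 18L, 18L, arr, mirror = FALSE)
  }

  # ---- periodicity: -shift * speed * T cross term ----
  sh <- c(1L, 66L + c(1L, 5L, 9L, 13L))
  wsum <- -sum(yper[sh])
  put(lay$i_speed, lay$i_T, wsum)
  put(lay$i_T, lay$i_speed, wsum)

  iv <- unlist(ii[seq_len(nb)]); jv <- unlist(jj[seq_len(nb)])
  xv <- unlist(xx[seq_len(nb)])
  keep <- xv != 0
  Matrix::sparseMatrix(i = iv[keep], j = jv[keep], x = xv[keep],
                       dims = c(nz, nz))
}
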