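#' Protocol-specific model subset selection
#'
#' Applies the per-model b-value selection rules used when fitting tensor
#' and kurtosis models to the two protocols. For a Cartesian-grid (CS-DSI)
#' scheme, the tensor model uses the low-b grid samples with
#' `|q|^2 <= 5` (28 DWIs on the radius-5 grid, b up to about 1,300 s/mm^2)
#' and the kurtosis model all samples with b <= 3,000 s/mm^2 (85 DWIs);
#' for a multi-shell scheme, the tensor model uses the innermost
#' (b = 1,000) shell and the kurtosis model all shells.
#'
#' @param scheme A [SamplingScheme-class]. Grid-derived schemes are
#'   recognized by their grid indices.
#' @param model `"dt"` or `"kurtosis"`.
#' @param grid The parent [CartesianQGrid-class] (needed for grid schemes
#'   to resolve `|q|^2` bounds; defaults to the radius-5, b 6800 grid).
#' @return A [SamplingScheme-class] subset (diffusion-weighted entries
#'   only; keep b = 0 entries separately for fitting).
#' @examples
#' g <- buildGrid(5L, 6800)
#' s <- generateCsScheme(g, 2.3, seed = 1L)
#' nDwi(selectModelSubset(s, "kurtosis"))   # 85
#' @export
selectModelSubset <- function(scheme, model = c("dt", "kurtosis"),
                              grid = buildGrid(5L, 6800)) {
  model <- match.arg(model)
  e <- scheme@entries
  onGrid <- any(!is.na(e$qx) & e$bval > 0)
  if (onGrid) {
    q2max <- if (model == "dt") 5 else
      floor(grid@radius^2 * 3000 / grid@bMax + 1e-9)
    bHi <- grid@bMax * q2max / grid@radius^2
    out <- selectByBvalue(scheme, .Machine$double.eps, bHi + 1e-6)
  } else {
    b <- unique(e$bval[e$bval > 0])
    if (model == "dt") {
      inner <- min(b)
      out <- selectByBvalue(scheme, inner - 1e-6, inner + 1e-6)
    } else {
      out <- selectByBvalue(scheme, .Machine$double.eps, max(b) + 1e-6)
    }
  }
  out
}

# Second-order design monomials for a direction matrix g (n x 3):
# [gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz] (matching D packed as
# Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
designD <- function(g) {
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

packTensor <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3L, 3L)
}

#' Order of the 15 unique kurtosis tensor elements
#'
#' The fully symmetric fourth-order tensor W is stored as its 15 unique
#' elements with multiplicity absorbed into the design: three pure terms
#' (xxxx, yyyy, zzzz), six of the form xxxy (multiplicity 4), three of the
#' form xxyy (multiplicity 6) and three of the form xxyz (multiplicity 12).
#'
#' @return Character vector of element names in storage order.
#' @export
dkiTermOrder <- function() c(
  "xxxx", "yyyy", "zzzz",
  "xxxy", "xxxz", "xyyy", "yyyz", "xzzz", "yzzz",
  "xxyy", "xxzz", "yyzz",
  "xxyz", "xyyz", "xyzz")

# Fourth-order design monomials with multiplicities, matching
# dkiTermOrder().
designW <- function(g) {
  x <- g[, 1]; y <- g[, 2]; z <- g[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * x * y^3, 4 * y^3 * z,
        4 * x * z^3, 4 * y * z^3,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * x * y^2 * z, 12 * x * y * z^2)
}

# Evaluate W(g) = sum_ijkl W g g g g for each row of g.
evalW <- function(w15, g) drop(designW(g) %*% w15)

#' Fit the diffusion tensor by weighted linear least squares
#'
#' Two-pass WLLS on the log signal: an ordinary least-squares pass gives
#' predicted signals whose squares serve as weights for the definitive fit
#' (the standard heteroscedasticity correction for log-linearized diffusion
#' data). Scalar maps come from the eigendecomposition; negative
#' eigenvalues are clamped to zero for the scalar maps and flagged.
#'
#' @param signals Signal vector (same length as the scheme subset; include
#'   b = 0 entries for S0 estimation).
#' @param scheme A [SamplingScheme-class] holding the matching entries.
#' @return A [TensorFit-class].
#' @export
fitDti <- function(signals, scheme) {
  e <- scheme@entries
  if (length(signals) != nrow(e))
    stop("signals must match scheme entries")
  g <- as.matrix(e[, c("dx", "dy", "dz")])
  b <- e$bval
  ndir <- qr(designD(g[b > 0, , drop = FALSE]))$rank
  if (sum(b > 0) < 6L || ndir < 6L)
    stop("rank-deficient design: need >= 6 non-coplanar directions, got rank ",
         ndir)
  if (any(signals <= 0)) stop("signals must be positive for the log fit")
  X <- cbind(1, -b * designD(g))
  ly <- log(signals)
  beta <- qr.solve(X, ly)                      # OLS pass
  wgt <- exp(X %*% beta)^2                     # squared predicted signals
  XtW <- t(X * as.numeric(wgt))
  beta <- solve(XtW %*% X, XtW %*% ly)
  D <- packTensor(beta[-1L])
  s0 <- exp(beta[1L])
  eig <- eigen(D, symmetric = TRUE)
  ev <- eig$values
  clamped <- any(ev < 0)
  evc <- pmax(ev, 0)
  sc <- tensorScalars(evc)
  pred <- exp(X %*% beta)
  new("TensorFit", tensor = D, s0 = s0, fa = sc$fa, md = sc$md,
      ad = sc$ad, rd = sc$rd, evals = ev, evecs = eig$vectors,
      nmse = sum((signals - pred)^2) / sum(signals^2),
      clamped = clamped)
}

#' Fit the diffusion kurtosis model with directional constraints
#'
#' Fits `ln S = ln S0 - b D(g) + (b^2/6) MD^2 K(g)` by weighted linear
#' least squares over the 22 tensor parameters (6 for D, 15 for W, plus
#' ln S0), then enforces the robustness constraints
#' `Kmin <= K(g) <= Kmax` and `D(g) >= 0` on all fitted directions via a
#' quadratic program (sequential QP: the constraint bounds, which involve
#' D(g), are rebuilt from the current iterate until stable). Scalar
#' kurtosis maps: MK as the mean apparent kurtosis over a uniform
#' direction set (642-point tessellation), AK along the principal
#' eigenvector, RK as the mean over directions perpendicular to it.
#'
#' @param signals Positive signal vector.
#' @param scheme Matching [SamplingScheme-class] (needs >= 2 distinct
#'   nonzero b-values and >= 22 samples).
#' @param constraints List with `Kmin` and `Kmax` (defaults 0 and 3).
#' @return A [KurtosisFit-class].
#' @export
fitDki <- function(signals, scheme, constraints = list(Kmin = 0, Kmax = 3)) {
  e <- scheme@entries
  if (length(signals) != nrow(e))
    stop("signals must match scheme entries")
  bnz <- unique(round(e$bval[e$bval > 0], 6))
  if (length(bnz) < 2L)
    stop("kurtosis is unidentifiable from a single nonzero b-value")
  if (nrow(e) < 22L) stop("need >= 22 samples for the kurtosis fit")
  if (any(signals <= 0)) stop("signals must be positive for the log fit")
  g <- as.matrix(e[, c("dx", "dy", "dz")])
  b <- e$bval
  # parameters: [ln S0, D(6), V(15)] with V = MD^2 * W
  X <- cbind(1, -b * designD(g), (b^2 / 6) * designW(g))
  ly <- log(signals)
  beta <- qr.solve(X, ly)
  wgt <- as.numeric(exp(X %*% beta))^2
  XtW <- t(X * wgt)
  beta <- solve(XtW %*% X, XtW %*% ly)

  Kmin <- constraints$Kmin
  Kmax <- constraints$Kmax
  gd <- unique(g[b > 0, , drop = FALSE])
  A2 <- designD(gd)
  A4 <- designW(gd)
  constrained <- FALSE
  for (pass in 1:5) {
    Dg <- drop(A2 %*% beta[2:7])
    Vg <- drop(A4 %*% beta[8:22])
    Kg <- Vg / pmax(Dg, 1e-12)^2
    viol <- any(Dg < -1e-12) || any(Kg < Kmin - 1e-9) ||
      any(Kg > Kmax + 1e-9)
    if (!viol) break
    constrained <- TRUE
    # linear constraints at the current D(g):  A x <= b
    Dg2 <- pmax(Dg, 1e-12)^2
    Acon <- rbind(
      cbind(0, -A2, matrix(0, nrow(A2), 15L)),          # -D(g) <= 0
      cbind(0, matrix(0, nrow(A4), 6L), -A4),           # -V(g) <= -Kmin D^2
      cbind(0, matrix(0, nrow(A4), 6L), A4))            #  V(g) <=  Kmax D^2
    bcon <- c(rep(0, nrow(A2)), -Kmin * Dg2, Kmax * Dg2)
    H <- XtW %*% X
    H <- (H + t(H)) / 2
    f <- -drop(XtW %*% ly)
    sol <- tryCatch(
      pracma::quadprog(H, f, A = Acon, b = bcon),
      error = function(err) NULL)
    if (is.null(sol)) break
    betaNew <- sol$xmin
    if (max(abs(betaNew - beta)) < 1e-12) { beta <- betaNew; break }
    beta <- betaNew
  }

  D <- packTensor(beta[2:7])
  eig <- eigen(D, symmetric = TRUE)
  ev <- eig$values
  sc <- tensorScalars(pmax(ev, 0))
  mdVal <- sc$md
  w15 <- if (mdVal > 0) beta[8:22] / mdVal^2 else beta[8:22] * 0

  kApp <- function(u) {
    Dg <- drop(designD(u) %*% beta[2:7])
    Vg <- drop(designW(u) %*% beta[8:22])
    Vg / pmax(Dg, 1e-12)^2
  }
  dirSet <- sphereTessellation(3L)$vertices
  mk <- mean(kApp(dirSet))
  e1 <- eig$vectors[, 1L]
  ak <- kApp(matrix(e1, 1L))
  # perpendicular circle
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- ref - sum(ref * e1) * e1; p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(e1[2] * p1[3] - e1[3] * p1[2],
          e1[3] * p1[1] - e1[1] * p1[3],
          e1[1] * p1[2] - e1[2] * p1[1])
  ang <- seq(0, pi, length.out = 37L)[-37L]
  perp <- outer(cos(ang), p1) + outer(sin(ang), p2)
  rk <- mean(kApp(perp))

  pred <- exp(X %*% beta)
  new("KurtosisFit", tensor = D, wTensor = as.numeric(w15), s0 = exp(beta[1L]),
      fa = sc$fa, md = sc$md, ad = sc$ad, rd = sc$rd,
      mk = mk, ak = ak, rk = rk, evals = ev, evecs = eig$vectors,
      nmse = sum((signals - pred)^2) / sum(signals^2),
      constrained = constrained)
}

#' Apparent kurtosis along given directions
#'
#' `K(g) = MD^2 * W(g) / D(g)^2`, the directional apparent kurtosis of a
#' fitted kurtosis model. For a mixture of Gaussian compartments this
#' equals `3 * Var(D_g) / E[D_g]^2` of the compartment projections in the
#' low-b limit.
#'
#' @param fit A [KurtosisFit-class].
#' @param g Unit direction matrix (n x 3) or single 3-vector.
#' @return Numeric vector of apparent kurtosis values.
#' @export
directionalKurtosis <- function(fit, g) {
  if (is.null(dim(g))) g <- matrix(g, 1L)
  Dg <- drop(designD(g) %*% c(fit@tensor[1, 1], fit@tensor[2, 2],
                              fit@tensor[3, 3], fit@tensor[1, 2],
                              fit@tensor[1, 3], fit@tensor[2, 3]))
  md <- mean(diag(fit@tensor))
  Wg <- evalW(fit@wTensor, g)
  md^2 * Wg / pmax(Dg, 1e-12)^2
}
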