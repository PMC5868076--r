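#' REML estimation of random regression variance components
#'
#' Estimates the coefficient covariance matrices G (additive genetic,
#' distributed \eqn{u \sim N(0, K \otimes G)}) and P (permanent
#' environment, \eqn{p \sim N(0, I \otimes P)}) and the residual variance
#' \eqn{\sigma_e^2} for the no-SNP test-day model, the first step of the
#' two-step (P3D) strategy: components are estimated once here and then
#' held fixed for every SNP test.
#'
#' The estimator works on Henderson's mixed model equations. Iterations
#' are EM-REML updates (monotone in the restricted log-likelihood), with
#' an optional average-information (AI) acceleration: after a few EM
#' warm-up rounds a Newton step on the AI matrix is attempted and halved /
#' abandoned in favour of plain EM whenever it would leave the PSD cone or
#' decrease the restricted log-likelihood. G and P are kept symmetric PSD
#' by eigenvalue truncation after every update (a tiny positive floor
#' keeps them invertible inside the MME).
#'
#' @param pheno A [phenotype_table()].
#' @param K A `kinship_matrix` covering all phenotyped animals. Ignored
#'   when `include_genetic = FALSE`.
#' @param mean_spec,add_spec,perm_spec [basis_spec()]s as in
#'   [build_design()].
#' @param init Optional [variance_components()] starting values. Default:
#'   \eqn{G = P = 0.1\,\mathrm{var}(y)\,I}, \eqn{\sigma_e^2 = 0.8\,
#'   \mathrm{var}(y)}.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param method `"ai"` (EM warm-up + safeguarded AI steps, default) or
#'   `"em"` (plain EM-REML).
#' @param include_genetic If `FALSE`, fits the no-polygenic comparator
#'   model (no u term; only P and sigma2_e estimated).
#' @param max_records Guard on the number of records for the dense solver
#'   (default 20000).
#' @param verbose Print the likelihood trace.
#' @return A [variance_components()] with attribute `"convergence"`: list
#'   with `iterations`, `logl` (restricted log-likelihood trace),
#'   `final_logl`, `grad_norm`, `converged`.
#' @export
reml_estimate <- function(pheno, K = NULL, mean_spec, add_spec,
                          perm_spec = add_spec, init = NULL,
                          max_iter = 200L, tol = 1e-6,
                          method = c("ai", "em"),
                          include_genetic = TRUE,
                          max_records = 20000L, verbose = FALSE) {
  method <- match.arg(method)
  if (nrow(pheno) > max_records)
    stop(sprintf(paste0("%d records exceed the dense-REML guard of %d; ",
                        "raise `max_records` only with enough memory/time"),
                 nrow(pheno), max_records))
  ids <- sort(unique(as.character(pheno$animal_id)))
  if (include_genetic) {
    if (is.null(K)) stop("K is required when include_genetic = TRUE")
    if (!all(ids %in% K$individual_ids))
      stop("kinship matrix is missing phenotyped animal(s)")
    panel <- K$individual_ids[K$individual_ids %in% ids]
  } else {
    panel <- ids
  }
  design <- build_design(pheno, panel, mean_spec, add_spec, perm_spec)
  y <- design$y
  N <- length(y); n <- design$n_ind
  q1 <- ncol(design$Phi_add); q2 <- ncol(design$Phi_perm)
  X <- design$X; p_fix <- ncol(X)

  Qm <- if (include_genetic) design_Q(design) else NULL
  Zm <- design_Z(design)
  Wm <- cbind(Qm, Zm)
  nu <- if (include_genetic) n * q1 else 0L
  np <- n * q2
  iu <- if (nu) p_fix + seq_len(nu) else integer(0)
  ip <- p_fix + nu + seq_len(np)

  # data cross-products, fixed over iterations
  Call_data <- crossprod(cbind(X, Wm))
  rhs_data <- drop(crossprod(cbind(X, Wm), y))
  yty <- sum(y^2)

  # A marker-derived K built with sample allele frequencies is singular
  # (the centering annihilates the all-ones vector), and a naive tiny ridge
  # makes K^-1 so ill-conditioned that the EM trace terms lose monotonicity.
  # Standard genomic-evaluation practice is to blend K toward the identity;
  # here K's eigenvalues are floored at 1% of its mean diagonal, which
  # bounds the condition of the mixed model equations.
  Kinv <- NULL; logdetK <- 0; Ksub <- NULL
  if (include_genetic) {
    kk <- match(panel, K$individual_ids)
    Ksub <- (K$values[kk, kk] + t(K$values[kk, kk])) / 2
    egK <- eigen(Ksub, symmetric = TRUE)
    flo <- 0.01 * mean(diag(Ksub))
    if (min(egK$values) < flo) {
      message(sprintf("kinship eigenvalue floor applied to %d of %d eigenvalues",
                      sum(egK$values < flo), n))
      ev <- pmax(egK$values, flo)
      Ksub <- egK$vectors %*% (ev * t(egK$vectors))
      Ksub <- (Ksub + t(Ksub)) / 2
    } else {
      ev <- egK$values
    }
    Kinv <- egK$vectors %*% ((1 / ev) * t(egK$vectors))
    Kinv <- (Kinv + t(Kinv)) / 2
    logdetK <- sum(log(ev))
  }

  vy <- stats::var(y)
  if (is.null(init)) {
    G0 <- diag(0.1 * vy, q1)
    P0 <- diag(0.1 * vy, q2)
    s0 <- 0.8 * vy
  } else {
    stopifnot(inherits(init, "variance_components"))
    if (include_genetic && nrow(init$G) != q1)
      stop("init G dimension does not match the additive basis order")
    if (nrow(init$P) != q2)
      stop("init P dimension does not match the permanent-environment basis order")
    G0 <- init$G; P0 <- init$P; s0 <- init$sigma2_e
  }

  floor_psd <- function(M) {
    M <- (M + t(M)) / 2
    eg <- eigen(M, symmetric = TRUE)
    flo <- max(1e-10 * max(eg$values, 0), 1e-12)
    ev <- pmax(eg$values, flo)
    M2 <- eg$vectors %*% (ev * t(eg$vectors))
    (M2 + t(M2)) / 2
  }
  G <- if (include_genetic) floor_psd(G0) else NULL
  P <- floor_psd(P0)
  s2 <- s0

  blk_trace <- function(Cblk, Mout, q) {
    # T[j,k] = sum_{m,n} Mout[m,n] * Cblk[(m-1)q+j, (n-1)q+k]
    T <- matrix(0, q, q)
    nn <- nrow(Cblk) / q
    for (j in seq_len(q)) for (k in seq_len(q)) {
      sj <- seq(j, nn * q, by = q); sk <- seq(k, nn * q, by = q)
      T[j, k] <- if (is.null(Mout)) sum(Cblk[cbind(sj, sk)])
                 else sum(Mout * Cblk[sj, sk])
    }
    T
  }

  assemble <- function(G, P, s2) {
    C <- Call_data / s2
    if (include_genetic) {
      Ginv <- chol2inv(chol(G))
      C[iu, iu] <- C[iu, iu] + kronecker(Kinv, Ginv)
    }
    Pinv <- chol2inv(chol(P))
    for (j in seq_len(q2)) for (k in seq_len(q2)) {
      sj <- ip[seq(j, np, by = q2)]; sk <- ip[seq(k, np, by = q2)]
      idx <- cbind(sj, sk)
      C[idx] <- C[idx] + Pinv[j, k]
    }
    C
  }

  # restricted log-likelihood (up to an additive constant) and the MME
  # solution for a parameter triple
  evaluate <- function(G, P, s2) {
    C <- assemble(G, P, s2)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    sol <- backsolve(ch, backsolve(ch, rhs_data / s2, transpose = TRUE))
    yPy <- (yty - sum(sol * rhs_data)) / s2
    logdetC <- 2 * sum(log(diag(ch)))
    logdetA <- (if (include_genetic)
                  q1 * logdetK + n * determinant(G)$modulus[1] else 0) +
      n * determinant(P)$modulus[1]
    logl <- -0.5 * (N * log(s2) + logdetA + logdetC + yPy)
    list(chol = ch, sol = sol, logl = logl, yPy = yPy)
  }

  em_update <- function(ev, G, P, s2) {
    Cinv <- chol2inv(ev$chol)
    sol <- ev$sol
    if (include_genetic) {
      Um <- matrix(sol[iu], nrow = n, ncol = q1, byrow = TRUE)
      Tg <- blk_trace(Cinv[iu, iu, drop = FALSE], Kinv, q1)
      G_new <- (crossprod(Um, Kinv %*% Um) + Tg) / n
    } else G_new <- NULL
    Pm <- matrix(sol[ip], nrow = n, ncol = q2, byrow = TRUE)
    Tp <- blk_trace(Cinv[ip, ip, drop = FALSE], NULL, q2)
    P_new <- (crossprod(Pm) + Tp) / n
    # Laird-Ware EM residual update (monotone): E[e'e | y]/N with all
    # effects' uncertainty added through tr(C^-1 D'D)
    ehat <- y - drop(cbind(X, Wm) %*% sol)
    s2_new <- (sum(ehat^2) + sum(Cinv * Call_data)) / N
    list(G = if (include_genetic) floor_psd(G_new) else NULL,
         P = floor_psd(P_new), s2 = max(s2_new, 1e-10 * vy))
  }

  vech_idx <- function(q) which(lower.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)

  ai_update <- function(ev, G, P, s2) {
    Cinv <- chol2inv(ev$chol)
    sol <- ev$sol
    fit <- drop(cbind(X, Wm) %*% sol)
    Py <- (y - fit) / s2
    Ginv <- if (include_genetic) chol2inv(chol(G)) else NULL
    Pinv <- chol2inv(chol(P))

    igx <- if (include_genetic) vech_idx(q1) else NULL
    ipx <- vech_idx(q2)
    n_par <- (if (include_genetic) nrow(igx) else 0) + nrow(ipx) + 1L

    # symmetric elementary matrix: dG/dG_jk (single 1 on the diagonal when j=k)
    elem <- function(q, j, k) {
      E <- matrix(0, q, q); E[j, k] <- 1; E[k, j] <- 1
      E
    }

    # dV/dtheta_i %*% Py for every parameter
    fs <- matrix(0, N, n_par)
    col <- 0L
    if (include_genetic) {
      vQ <- drop(crossprod(Qm, Py))
      VmQ <- matrix(vQ, nrow = n, ncol = q1, byrow = TRUE)
      for (r in seq_len(nrow(igx))) {
        j <- igx[r, 1]; k <- igx[r, 2]
        E <- elem(q1, j, k)
        Fm <- (Ksub %*% VmQ) %*% E
        col <- col + 1L
        fs[, col] <- rowSums(design$Phi_add * Fm[design$record_ind, , drop = FALSE])
      }
    }
    vZ <- drop(crossprod(Zm, Py))
    VmZ <- matrix(vZ, nrow = n, ncol = q2, byrow = TRUE)
    for (r in seq_len(nrow(ipx))) {
      j <- ipx[r, 1]; k <- ipx[r, 2]
      E <- elem(q2, j, k)
      Fm <- VmZ %*% E
      col <- col + 1L
      fs[, col] <- rowSums(design$Phi_perm * Fm[design$record_ind, , drop = FALSE])
    }
    fs[, n_par] <- Py

    # P f for every column via the MME absorption identity
    rhs_f <- crossprod(cbind(X, Wm), fs) / s2
    sol_f <- backsolve(ev$chol, backsolve(ev$chol, rhs_f, transpose = TRUE))
    Pf <- (fs - cbind(X, Wm) %*% sol_f) / s2

    AI <- 0.5 * crossprod(fs, Pf)

    # gradient: -0.5 ( tr(P dV) - Py' dV Py )
    score <- numeric(n_par)
    col <- 0L
    if (include_genetic) {
      Tg <- blk_trace(Cinv[iu, iu, drop = FALSE], Kinv, q1)
      for (r in seq_len(nrow(igx))) {
        j <- igx[r, 1]; k <- igx[r, 2]
        E <- elem(q1, j, k)
        B <- Ginv %*% E %*% Ginv
        trPdV <- n * sum(diag(Ginv %*% E)) - sum(B * Tg)
        col <- col + 1L
        score[col] <- -0.5 * (trPdV - sum(Py * fs[, col]))
      }
    }
    Tp <- blk_trace(Cinv[ip, ip, drop = FALSE], NULL, q2)
    for (r in seq_len(nrow(ipx))) {
      j <- ipx[r, 1]; k <- ipx[r, 2]
      E <- elem(q2, j, k)
      B <- Pinv %*% E %*% Pinv
      trPdV <- n * sum(diag(Pinv %*% E)) - sum(B * Tp)
      col <- col + 1L
      score[col] <- -0.5 * (trPdV - sum(Py * fs[, col]))
    }
    trP <- N / s2 - sum(Cinv * Call_data) / s2^2
    score[n_par] <- -0.5 * (trP - sum(Py * fs[, n_par]))

    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    list(delta = delta, score = score)
  }

  apply_delta <- function(G, P, s2, delta, stepsize) {
    col <- 0L
    if (include_genetic) {
      igx <- vech_idx(q1)
      for (r in seq_len(nrow(igx))) {
        col <- col + 1L
        j <- igx[r, 1]; k <- igx[r, 2]
        G[j, k] <- G[j, k] + stepsize * delta[col]
        G[k, j] <- G[j, k]
      }
    }
    ipx <- vech_idx(q2)
    for (r in seq_len(nrow(ipx))) {
      col <- col + 1L
      j <- ipx[r, 1]; k <- ipx[r, 2]
      P[j, k] <- P[j, k] + stepsize * delta[col]
      P[k, j] <- P[j, k]
    }
    s2 <- s2 + stepsize * delta[col + 1L]
    if (s2 <= 0) return(NULL)
    eg_ok <- function(M) min(eigen((M + t(M)) / 2, symmetric = TRUE,
                                   only.values = TRUE)$values) > -1e-8 * max(sum(diag(M)), 1)
    if (include_genetic && !eg_ok(G)) return(NULL)
    if (!eg_ok(P)) return(NULL)
    list(G = if (include_genetic) floor_psd(G) else NULL,
         P = floor_psd(P), s2 = s2)
  }

  ev <- evaluate(G, P, s2)
  if (is.null(ev)) stop("initial variance components give a singular system")
  logl_trace <- ev$logl
  converged <- FALSE
  grad_norm <- NA_real_
  n_em_warmup <- 3L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    stepped <- FALSE
    if (method == "ai" && it > n_em_warmup) {
      ai <- ai_update(ev, G, P, s2)
      grad_norm <- max(abs(ai$score))
      if (!is.null(ai$delta) && all(is.finite(ai$delta))) {
        stepsize <- 1
        for (h in 1:5) {
          cand <- apply_delta(G, P, s2, ai$delta, stepsize)
          if (!is.null(cand)) {
            ev_c <- evaluate(cand$G, cand$P, cand$s2)
            if (!is.null(ev_c) && ev_c$logl >= ev$logl - 1e-10) {
              G <- cand$G; P <- cand$P; s2 <- cand$s2
              ev <- ev_c; stepped <- TRUE
              break
            }
          }
          stepsize <- stepsize / 2
        }
      }
    }
    if (!stepped) {
      upd <- em_update(ev, G, P, s2)
      G <- upd$G; P <- upd$P; s2 <- upd$s2
      ev <- evaluate(G, P, s2)
      if (is.null(ev)) stop("EM update produced a singular system")
    }
    logl_trace <- c(logl_trace, ev$logl)
    if (verbose) message(sprintf("iter %3d  logL %.6f", it, ev$logl))
    if (abs(logl_trace[it + 1L] - logl_trace[it]) < tol) {
      converged <- TRUE
      break
    }
  }

  out <- variance_components(
    G = if (include_genetic) G else matrix(0, q1, q1),
    P = P, sigma2_e = s2)
  attr(out, "convergence") <- list(iterations = it, logl = logl_trace,
                                   final_logl = ev$logl,
                                   grad_norm = grad_norm,
                                   converged = converged)
  if (!converged)
    warning(sprintf("REML did not converge in %d iterations (last logL change %.3g)",
                    it, abs(diff(utils::tail(logl_trace, 2L)))))
  out
}

#' Write variance components to a plain-text file
#'
#' Layout: a `G` block header with its dimension, the lower triangle row
#' by row, then the same for `P`, then `SIGMA2E` with a single value.
#' `#` starts a comment. Values are written with full precision so
#' `read_varcomp(write_varcomp(vc))` round-trips exactly.
#'
#' @param vc A [variance_components()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_varcomp <- function(vc, path) {
  stopifnot(inherits(vc, "variance_components"))
  fmt_tri <- function(M) {
    vapply(seq_len(nrow(M)), function(i)
      paste(sprintf("%.17g", M[i, seq_len(i)]), collapse = " "), character(1))
  }
  lines <- c("# variance components: G (additive), P (permanent env), SIGMA2E",
             sprintf("G %d", nrow(vc$G)), fmt_tri(vc$G),
             sprintf("P %d", nrow(vc$P)), fmt_tri(vc$P),
             "SIGMA2E", sprintf("%.17g", vc$sigma2_e))
  writeLines(lines, path)
  invisible(path)
}

#' Read variance components from the plain-text layout
#'
#' @param path File written by [write_varcomp()] (or by external software
#'   following the same layout).
#' @param add_order,perm_order Optional expected basis orders; a dimension
#'   mismatch is an error stating both.
#' @return A [variance_components()].
#' @export
read_varcomp <- function(path, add_order = NULL, perm_order = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  pos <- 1L
  read_block <- function(label) {
    hdr <- strsplit(lines[pos], "\\s+")[[1]]
    if (toupper(hdr[1]) != label)
      stop(sprintf("expected block '%s' at line %d, found '%s'",
                   label, pos, hdr[1]))
    d <- as.integer(hdr[2])
    M <- matrix(0, d, d)
    for (i in seq_len(d)) {
      vals <- as.numeric(strsplit(lines[pos + i], "\\s+")[[1]])
      if (length(vals) != i)
        stop(sprintf("row %d of block %s must have %d value(s)", i, label, i))
      M[i, seq_len(i)] <- vals
      M[seq_len(i), i] <- vals
    }
    pos <<- pos + d + 1L
    M
  }
  G <- read_block("G")
  P <- read_block("P")
  if (toupper(lines[pos]) != "SIGMA2E")
    stop("expected block 'SIGMA2E' after P")
  s2 <- as.numeric(lines[pos + 1L])
  if (!is.null(add_order) && nrow(G) != add_order + 1L)
    stop(sprintf("file G is %dx%d but the configured additive order %d needs %dx%d",
                 nrow(G), nrow(G), add_order, add_order + 1L, add_order + 1L))
  if (!is.null(perm_order) && nrow(P) != perm_order + 1L)
    stop(sprintf("file P is %dx%d but the configured permanent-environment order %d needs %dx%d",
                 nrow(P), nrow(P), perm_order, perm_order + 1L, perm_order + 1L))
  variance_components(G, P, s2)
}
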