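# Model catalogue: every fit is a site-class mixture over two branch
# partitions (background/reference = column 1, foreground/test = column 2).
# A model definition supplies the free-parameter layout in transformed
# (unconstrained-within-bounds) space and the mapping to mixture structure.
#
# Bounds follow the conventional optimizer caps: omega in [1e-4, 999]
# (the 999 cap is visible in reported fits as omega ~ 999), kappa in
# [0.05, 50], selection intensity k in [0.01, 50].

.OMEGA_MIN <- 1e-4
.OMEGA_MAX <- 999
.KAPPA_MIN <- 0.05
.KAPPA_MAX <- 50
.K_MIN <- 0.01
.K_MAX <- 50
.ALR_BOUND <- 20  # proportions never reach exact 0 (floor ~ exp(-20))

.codonModels <- c("M0", "twoRatio", "twoRatioNeutralFg", "modelA",
                  "modelANull", "busted", "bustedNull", "relaxAlt",
                  "relaxNull")

# parameter descriptors: name, transform (log / alr), lower, upper (on the
# transformed scale), default initial value (natural scale)
.parSpec <- function(model) {
  L <- function(name, lo, hi, init)
    list(name = name, lower = log(lo), upper = log(hi), init = log(init))
  A <- function(name, init)  # alr coordinate
    list(name = name, lower = -.ALR_BOUND, upper = .ALR_BOUND, init = init)
  kap <- L("kappa", .KAPPA_MIN, .KAPPA_MAX, 2)
  switch(model,
    M0 = list(kap, L("omega", .OMEGA_MIN, .OMEGA_MAX, 0.3)),
    twoRatio = list(kap, L("omegaBg", .OMEGA_MIN, .OMEGA_MAX, 0.3),
                    L("omegaFg", .OMEGA_MIN, .OMEGA_MAX, 0.5)),
    twoRatioNeutralFg = list(kap, L("omegaBg", .OMEGA_MIN, .OMEGA_MAX, 0.3)),
    modelA = list(kap, L("omega0", .OMEGA_MIN, 1, 0.1),
                  L("omega2", 1, .OMEGA_MAX, 2),
                  A("alr0", log(0.70 / 0.10)), A("alr1", log(0.20 / 0.10))),
    modelANull = list(kap, L("omega0", .OMEGA_MIN, 1, 0.1),
                      A("alr0", log(0.70 / 0.10)),
                      A("alr1", log(0.20 / 0.10))),
    busted = list(kap, L("omegaRatio1", 1e-4, 1, 0.3),
                  L("omega2", .OMEGA_MIN, 1, 0.3),
                  L("omega3", 1, .OMEGA_MAX, 2),
                  A("alr0", log(0.70 / 0.05)), A("alr1", log(0.25 / 0.05))),
    bustedNull = list(kap, L("omegaRatio1", 1e-4, 1, 0.3),
                      L("omega2", .OMEGA_MIN, 1, 0.3),
                      A("alr0", log(0.70 / 0.05)),
                      A("alr1", log(0.25 / 0.05))),
    relaxAlt = list(kap, L("omegaRatio1", 1e-4, 1, 0.5),
                    L("omega2", .OMEGA_MIN, 1, 0.3),
                    L("omega3", 1, .OMEGA_MAX, 2),
                    A("alr0", log(0.70 / 0.05)), A("alr1", log(0.25 / 0.05)),
                    L("k", .K_MIN, .K_MAX, 1)),
    relaxNull = list(kap, L("omegaRatio1", 1e-4, 1, 0.5),
                     L("omega2", .OMEGA_MIN, 1, 0.3),
                     L("omega3", 1, .OMEGA_MAX, 2),
                     A("alr0", log(0.70 / 0.05)),
                     A("alr1", log(0.25 / 0.05))),
    stop("unknown model: ", model))
}

# additive log-ratio -> 3-simplex (p_last is the reference category)
.alrInv <- function(a1, a2) {
  e <- c(exp(a1), exp(a2), 1)
  e / sum(e)
}

# map a named natural-scale parameter list to mixture structure:
# list(kappa, classOmega (nclass x 2), classProp, mixture data.frame)
.modelStructure <- function(model, par) {
  k <- par$kappa
  if (model == "M0") {
    co <- matrix(par$omega, 1, 2)
    pr <- 1
    lab <- "all"
  } else if (model %in% c("twoRatio", "twoRatioNeutralFg")) {
    fg <- if (model == "twoRatio") par$omegaFg else 1
    co <- matrix(c(par$omegaBg, fg), 1, 2)
    pr <- 1
    lab <- "all"
  } else if (model %in% c("modelA", "modelANull")) {
    w0 <- par$omega0
    w2 <- if (model == "modelA") par$omega2 else 1
    p <- .alrInv(par$alr0, par$alr1)          # (p0, p1, p2)
    p2 <- p[3]
    pr <- c(p[1], p[2], p2 * p[1] / (p[1] + p[2]), p2 * p[2] / (p[1] + p[2]))
    co <- rbind(c(w0, w0), c(1, 1), c(w0, w2), c(1, w2))
    lab <- c("0", "1", "2a", "2b")
  } else if (model %in% c("busted", "bustedNull")) {
    w2 <- par$omega2
    w1 <- par$omegaRatio1 * w2
    w3 <- if (model == "busted") par$omega3 else 1
    pr <- .alrInv(par$alr0, par$alr1)
    co <- rbind(c(w1, w1), c(w2, w2), c(1, w3))
    lab <- c("1", "2", "3")
  } else if (model %in% c("relaxAlt", "relaxNull")) {
    w2 <- par$omega2
    w1 <- par$omegaRatio1 * w2
    w3 <- par$omega3
    kk <- if (model == "relaxAlt") par$k else 1
    ref <- c(w1, w2, w3)
    test <- pmin(pmax(ref, .Machine$double.xmin)^kk, 1e6)
    pr <- .alrInv(par$alr0, par$alr1)
    co <- cbind(ref, test)
    lab <- c("1", "2", "3")
  } else stop("unknown model: ", model)
  mix <- data.frame(class = lab, prop = pr,
                    omegaBackground = co[, 1], omegaForeground = co[, 2])
  list(kappa = k, classOmega = unname(co), classProp = pr, mixture = mix,
       k = if (model == "relaxAlt") par$k else
         if (model == "relaxNull") 1 else NULL)
}

# theta (transformed) -> named natural-scale list
.thetaToPar <- function(model, theta, spec, fix) {
  par <- list()
  j <- 0L
  for (s in spec) {
    if (s$name %in% names(fix)) {
      par[[s$name]] <- fix[[s$name]]
    } else {
      j <- j + 1L
      par[[s$name]] <- if (startsWith(s$name, "alr")) theta[j]
                       else exp(theta[j])
    }
  }
  par
}

# natural-scale value -> transformed coordinate for one descriptor
.toTheta <- function(s, value) {
  v <- if (startsWith(s$name, "alr")) value else log(value)
  min(max(v, s$lower), s$upper)
}
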