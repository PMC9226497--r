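# Independent reference implementations used as oracles. Each is written
# as a plain, direct transcription of the underlying arithmetic (scalar
# loops, closed forms), deliberately sharing no code with the package
# internals it checks.

# --- intrinsic-rate oracle: independently typed factor tables, scalar math
oracle_factor_table <- read.table(header = TRUE, text = "
aa acid_l acid_r base_l base_r
A   0.00   0.00   0.00   0.00
R  -0.59  -0.32   0.08   0.22
N  -0.58  -0.13   0.49   0.32
D   0.90   0.58   0.10  -0.18
C  -0.54  -0.46   0.62   0.55
E  -0.90   0.31  -0.11  -0.15
Q  -0.47  -0.27   0.06   0.20
G  -0.22   0.22   0.27   0.17
H   0.00   0.00  -0.10   0.14
I  -0.91  -0.59  -0.73  -0.23
L  -0.57  -0.13  -0.58  -0.21
K  -0.56  -0.29  -0.04   0.12
M  -0.64  -0.28  -0.01   0.11
F  -0.52  -0.43  -0.24   0.06
P     NA  -0.19     NA  -0.24
S  -0.44  -0.39   0.37   0.30
T  -0.79  -0.47  -0.07   0.20
W  -0.40  -0.44  -0.41  -0.11
Y  -0.41  -0.37  -0.27   0.05
V  -0.74  -0.30  -0.70  -0.14
", stringsAsFactors = FALSE)

oracle_kint <- function(sequence, pD, temperature_K) {
  tab <- oracle_factor_table
  row_of <- function(a) tab[tab$aa == a, ]
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  R_gas <- 8.314
  arrh <- function(Ea_kcal) {
    exp(-Ea_kcal * 4184 / R_gas * (1 / temperature_K - 1 / 293.15))
  }
  pKD <- 15.05 + (60.2 * 1000 / (R_gas * log(10))) *
    (1 / temperature_K - 1 / 293.15)
  k <- rep(NA_real_, n)
  for (i in 2:n) {
    if (aa[i] == "P") next
    AL <- row_of(aa[i])$acid_l
    BL <- row_of(aa[i])$base_l
    AR <- row_of(aa[i - 1])$acid_r
    BR <- row_of(aa[i - 1])$base_r
    if (i == 2) { AR <- AR + (-1.32); BR <- BR + 1.62 }
    if (i == n) { AL <- AL + 0.96; BL <- BL + (-1.80) }
    acid <- arrh(14) * 10^(1.62 + AL + AR) * 10^(-pD)
    base <- arrh(17) * 10^(10.18 + BL + BR) * 10^(pD - pKD)
    water <- arrh(19) * 10^(-1.5 + BL + BR)
    k[i] <- acid + base + water
  }
  k
}

# --- brute-force overlap-subtraction oracle: enumerate all ordered pairs
oracle_overlaps <- function(table, sigma_multiplier = 5) {
  spans <- unique(table[c("start", "end")])
  rows <- list()
  for (a in seq_len(nrow(spans))) for (b in seq_len(nrow(spans))) {
    sa <- spans$start[a]; ea <- spans$end[a]
    sb <- spans$start[b]; eb <- spans$end[b]
    if (!(sa <= sb && ea >= eb)) next            # a must contain b
    if ((ea - sa) == (eb - sb)) next             # strict containment
    if ((sa == sb) == (ea == eb)) next           # exactly one shared end
    region <- if (sa == sb) c(eb + 1L, ea) else c(sa, sb - 1L)
    ra <- table[table$start == sa & table$end == ea, ]
    rb <- table[table$start == sb & table$end == eb, ]
    for (t in intersect(ra$exposure_s, rb$exposure_s)) {
      ua <- ra$uptake_Da[ra$exposure_s == t]
      ub <- rb$uptake_Da[rb$exposure_s == t]
      va <- ra$sd_Da[ra$exposure_s == t]
      vb <- rb$sd_Da[rb$exposure_s == t]
      d <- ua - ub
      s <- sqrt(va^2 + vb^2)
      rows[[length(rows) + 1]] <- data.frame(
        region_start = region[1], region_end = region[2],
        long_start = sa, long_end = ea, short_start = sb, short_end = eb,
        exposure_s = t, uptake_Da = d, sd_Da = s,
        accepted = abs(d) > sigma_multiplier * s
      )
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$region_start, out$region_end, out$exposure_s), ]
}

# --- dense grid-search oracle for the single-exponential fit
oracle_grid_fit <- function(t, y, sd, A_range, k_range, nA = 240, nk = 240) {
  w <- ifelse(sd > 0, 1 / sd^2, 1)
  A_grid <- seq(A_range[1], A_range[2], length.out = nA)
  k_grid <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = nk))
  best <- c(NA, NA); best_sse <- Inf
  for (A in A_grid) for (k in k_grid) {
    sse <- sum(w * (y - A * (1 - exp(-k * t)))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(A, k) }
  }
  list(A = best[1], k = best[2], sse = best_sse,
       dA = diff(A_range) / (nA - 1))
}

# --- closed-form exposed area of two intersecting spheres
# accessible radii R1, R2, centre separation d < R1 + R2
oracle_two_sphere_exposed <- function(R1, R2, d) {
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * h1,
    4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# --- O(N^2) hydrogen-bond oracle: plain double loop over donors/acceptors
oracle_hbonds_frame <- function(atoms, d_cut = 3.5, theta_cut = 30) {
  water <- atoms$resid %in% c("HOH", "WAT", "TIP3", "SPC", "SOL")
  res_of <- paste(atoms$chain, atoms$resno)
  find1 <- function(cond) { w <- which(cond); if (length(w)) w[1] else NA }
  donors <- which(!water & atoms$elety == "N" & atoms$resid != "PRO")
  out <- NULL
  for (d in donors) {
    prev <- paste(atoms$chain[d], atoms$resno[d] - 1)
    if (is.na(find1(!water & atoms$elety == "C" & res_of == prev))) next
    h <- find1(res_of == res_of[d] & atoms$elety %in% c("H", "HN"))
    npos <- c(atoms$x[d], atoms$y[d], atoms$z[d])
    hpos <- c(atoms$x[h], atoms$y[h], atoms$z[h])
    check <- function(idx) {
      hit <- FALSE
      for (a in idx) {
        apos <- c(atoms$x[a], atoms$y[a], atoms$z[a])
        v <- apos - npos
        dist <- sqrt(sum(v^2))
        if (dist > d_cut || dist < 1e-6) next
        u <- hpos - npos
        ang <- acos(sum(v * u) / (dist * sqrt(sum(u^2)))) * 180 / pi
        if (ang <= theta_cut) { hit <- TRUE; break }
      }
      hit
    }
    prot_acc <- which(!water & substr(atoms$elety, 1, 1) == "O" &
                        res_of != res_of[d])
    prot_acc <- c(prot_acc, which(!water & atoms$resid == "HIS" &
                                    atoms$elety %in% c("ND1", "NE2") &
                                    res_of != res_of[d]))
    wat_acc <- which(water & substr(atoms$elety, 1, 1) == "O")
    out <- rbind(out, data.frame(
      residue = atoms$resno[d],
      bonded_to_protein = check(prot_acc),
      bonded_to_water = check(wat_acc)
    ))
  }
  out
}
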