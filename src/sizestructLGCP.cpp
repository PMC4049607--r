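// Latent-Gaussian Poisson model for size-structured trawl catches.
//
// Observation: count ~ Poisson(exp(eta)),
//   eta = mu(class) + sigma * xi(class, cell) + sigma_eps * eps(haul, class)
// with standardized latent fields (non-centered parameterization):
//   vec(xi) ~ N(0, S (x) C)   S = GMRF lattice correlation over water cells,
//                             C = joint (species/year, size) correlation,
//   eps_h  ~ N(0, C_block)    per haul, over the classes the haul observes.
// The marginal likelihood integrates (xi, eps) out by the Laplace
// approximation (TMB).
#define TMB_LIB_INIT R_init_sizestructLGCP
#include <TMB.hpp>

// oscillating size correlation rho(d) = exp(-d/a) (cos(bd) + c) / (1 + c)
template <class Type>
Type osc_corr(Type d, Type a, Type b, Type c) {
  return exp(-d / a) * (cos(b * d) + c) / (Type(1) + c);
}

// plain lower Cholesky factor (inputs are small PD matrices)
template <class Type>
matrix<Type> chol_lower(const matrix<Type> &A) {
  int n = A.rows();
  matrix<Type> L(n, n);
  L.setZero();
  for (int i = 0; i < n; i++) {
    for (int j = 0; j <= i; j++) {
      Type s = A(i, j);
      for (int k = 0; k < j; k++) s -= L(i, k) * L(j, k);
      if (i == j)
        L(i, i) = sqrt(s);
      else
        L(i, j) = s / L(j, j);
    }
  }
  return L;
}

// solve L x = b with L lower triangular
template <class Type>
vector<Type> forward_solve(const matrix<Type> &L, const vector<Type> &b) {
  int n = b.size();
  vector<Type> x(n);
  for (int i = 0; i < n; i++) {
    Type s = b(i);
    for (int k = 0; k < i; k++) s -= L(i, k) * x(k);
    x(i) = s / L(i, i);
  }
  return x;
}

// unit-row lower factor from hyperspherical angles; C = L L^T is a
// correlation matrix, PD for every finite theta
template <class Type>
matrix<Type> hypersphere_factor(const vector<Type> &theta, int k) {
  matrix<Type> L(k, k);
  L.setZero();
  L(0, 0) = Type(1);
  int pos = 0;
  for (int i = 1; i < k; i++) {
    Type sp = Type(1);
    for (int j = 0; j < i; j++) {
      Type ang = Type(M_PI) / (Type(1) + exp(-theta(pos + j)));
      L(i, j) = cos(ang) * sp;
      sp *= sin(ang);
    }
    L(i, i) = sp;
    pos += i;
  }
  return L;
}

template <class Type>
Type objective_function<Type>::operator()() {
  // spatial lattice
  DATA_INTEGER(M);          // number of water cells
  DATA_IVECTOR(nn);         // neighbour count per cell
  DATA_IVECTOR(edge_i);     // water-adjacent pairs, 0-based, i < j
  DATA_IVECTOR(edge_j);
  DATA_SCALAR(kappa);       // fixed GMRF coupling

  // joint class axis (group A classes first, then group B)
  DATA_INTEGER(K);
  DATA_INTEGER(kA);
  DATA_IVECTOR(class_group);   // 0/1 per joint class
  DATA_VECTOR(class_size);     // class midpoints (cm)
  DATA_INTEGER(transform_code);// 0 identity, 1 log, 2 logistic
  DATA_INTEGER(size_code);     // 0 structured, 1 unconstrained (hyperspherical)
  DATA_INTEGER(cross_code);    // 0 single group, 1 independent, 2 separable,
                               // 3 unconstrained cross-block R
  DATA_IVECTOR(osc_index);     // length 6: index into log_a/log_b/log_c per
                               // group (a_g, b_g, c_g); sharing = same index

  // hauls and observations
  DATA_IVECTOR(haul_block);    // observation block per haul (0-based)
  DATA_IVECTOR(eps_off);       // offset of each haul's eps segment
  DATA_IVECTOR(block_start);   // per block: first joint class
  DATA_IVECTOR(block_len);     //            number of classes
  DATA_IVECTOR(obs_class);     // per record: joint class (0-based)
  DATA_IVECTOR(obs_cell);      //             water cell of the haul
  DATA_IVECTOR(obs_eps);       //             index into eps
  DATA_VECTOR(obs_count);

  PARAMETER_VECTOR(mu);          // nuisance mean per joint class
  PARAMETER(log_sigma);          // structured-field magnitude
  PARAMETER(log_sigma_eps);      // nugget magnitude
  PARAMETER(log_delta);          // GMRF range parameter
  PARAMETER_VECTOR(log_a);       // oscillation decay scale(s)
  PARAMETER_VECTOR(log_b);       // oscillation frequency(ies)
  PARAMETER_VECTOR(log_c);       // oscillation offset(s)
  PARAMETER(L50);                // logistic transform centre (cm)
  PARAMETER(log_alpha);          // logistic transform rate
  PARAMETER_VECTOR(theta);       // hyperspherical angles (unconstrained corr)
  PARAMETER_VECTOR(Rvec);        // cross-block R, column-major kA x (K-kA)
  PARAMETER(rho_t);              // tanh^-1 of separable group correlation
  PARAMETER_VECTOR(xi);          // standardized structured field, K x M
  PARAMETER_VECTOR(eps);         // standardized nugget, one segment per haul

  Type sigma = exp(log_sigma);
  Type sigma_eps = exp(log_sigma_eps);
  Type delta = exp(log_delta);
  vector<Type> a = exp(log_a);
  vector<Type> b = exp(log_b);
  vector<Type> c = exp(log_c);
  Type alpha = exp(log_alpha);
  Type rho = tanh(rho_t);
  int kB = K - kA;

  Type nll = Type(0);
  const Type log2pi = log(Type(2) * Type(M_PI));

  // ---- joint (group, size) correlation C ----
  matrix<Type> C(K, K);
  if (size_code == 1) {
    matrix<Type> L = hypersphere_factor(theta, K);
    C = L * L.transpose();
    for (int i = 0; i < K; i++) C(i, i) = Type(1);
  } else {
    // transformed class midpoints
    vector<Type> t(K);
    for (int i = 0; i < K; i++) {
      if (transform_code == 0)
        t(i) = class_size(i);
      else if (transform_code == 1)
        t(i) = log(class_size(i));
      else
        t(i) = Type(1) / (Type(1) + exp(-alpha * (class_size(i) - L50)));
    }
    if (cross_code == 3) {
      // structured within-group blocks, unconstrained PD cross-block:
      // C = [ SA, Phi; Phi^T, SB ], Phi = LA V LB^T with V a contraction
      // of R, so the marginals SA, SB are exact and C is PD for any R
      matrix<Type> SA(kA, kA), SB(kB, kB);
      for (int i = 0; i < kA; i++)
        for (int j = 0; j < kA; j++)
          SA(i, j) = (i == j) ? Type(1)
            : osc_corr(fabs(t(i) - t(j)), a(osc_index(0)), b(osc_index(2)),
                       c(osc_index(4)));
      for (int i = 0; i < kB; i++)
        for (int j = 0; j < kB; j++)
          SB(i, j) = (i == j) ? Type(1)
            : osc_corr(fabs(t(kA + i) - t(kA + j)), a(osc_index(1)),
                       b(osc_index(3)), c(osc_index(5)));
      matrix<Type> R(kA, kB);
      for (int jj = 0; jj < kB; jj++)
        for (int ii = 0; ii < kA; ii++) R(ii, jj) = Rvec(ii + kA * jj);
      matrix<Type> G(kB, kB);
      G = R.transpose() * R;
      for (int i = 0; i < kB; i++) G(i, i) += Type(1);
      matrix<Type> U = chol_lower(G);          // G = U U^T
      matrix<Type> V(kA, kB);                  // V = R U^{-T}
      for (int i = 0; i < kA; i++) {
        vector<Type> ri(kB);
        for (int j = 0; j < kB; j++) ri(j) = R(i, j);
        vector<Type> vi = forward_solve(U, ri);
        for (int j = 0; j < kB; j++) V(i, j) = vi(j);
      }
      matrix<Type> LA = chol_lower(SA);
      matrix<Type> LB = chol_lower(SB);
      matrix<Type> Phi = LA * V * LB.transpose();
      C.topLeftCorner(kA, kA) = SA;
      C.bottomRightCorner(kB, kB) = SB;
      C.topRightCorner(kA, kB) = Phi;
      C.bottomLeftCorner(kB, kA) = Phi.transpose();
    } else {
      // structured correlation on the shared transformed scale; cross
      // entries carry the group correlation factor (0 under independence)
      Type cross_fac = (cross_code == 2) ? rho : Type(0);
      for (int i = 0; i < K; i++) {
        for (int j = 0; j < K; j++) {
          if (i == j) { C(i, j) = Type(1); continue; }
          int gi = class_group(i), gj = class_group(j);
          if (gi == gj) {
            C(i, j) = osc_corr(fabs(t(i) - t(j)), a(osc_index(gi)),
                               b(osc_index(2 + gi)), c(osc_index(4 + gi)));
          } else if (cross_code == 1) {
            C(i, j) = Type(0);
          } else {
            C(i, j) = cross_fac *
              osc_corr(fabs(t(i) - t(j)), a(osc_index(0)), b(osc_index(2)),
                       c(osc_index(4)));
          }
        }
      }
    }
  }

  // ---- spatial GMRF: Q = delta I + kappa (D - A); S = cov2cor(Q^-1) ----
  matrix<Type> Q(M, M);
  Q.setZero();
  for (int m = 0; m < M; m++) Q(m, m) = delta + kappa * Type(nn(m));
  for (int e = 0; e < edge_i.size(); e++) {
    Q(edge_i(e), edge_j(e)) = -kappa;
    Q(edge_j(e), edge_i(e)) = -kappa;
  }
  matrix<Type> Qinv = atomic::matinv(Q);
  vector<Type> d(M);
  for (int m = 0; m < M; m++) d(m) = Qinv(m, m);
  Type ldQ = atomic::logdet(Q);
  // S = D^{-1/2} Q^{-1} D^{-1/2}  =>  S^{-1} = D^{1/2} Q D^{1/2} (sparse),
  // log det S = -log det Q - sum log d
  Type logdetS = -ldQ - log(d).sum();

  // ---- prior of the structured field xi ~ N(0, S (x) C) ----
  matrix<Type> Ci = atomic::matinv(C);
  Type ldC = atomic::logdet(C);
  matrix<Type> Xi(K, M);
  for (int m = 0; m < M; m++)
    for (int r = 0; r < K; r++) Xi(r, m) = xi(r + K * m);
  matrix<Type> Y = Ci * Xi;
  Type quad = Type(0);
  for (int m = 0; m < M; m++) {
    Type s = Type(0);
    for (int r = 0; r < K; r++) s += Xi(r, m) * Y(r, m);
    quad += (delta + kappa * Type(nn(m))) * d(m) * s;
  }
  for (int e = 0; e < edge_i.size(); e++) {
    int i = edge_i(e), j = edge_j(e);
    Type s = Type(0);
    for (int r = 0; r < K; r++) s += Xi(r, i) * Y(r, j);
    quad += Type(2) * (-kappa * sqrt(d(i) * d(j))) * s;
  }
  nll += Type(0.5) * quad +
         Type(0.5) * (Type(K) * logdetS + Type(M) * ldC) +
         Type(0.5) * Type(K) * Type(M) * log2pi;

  // ---- prior of the nugget eps_h ~ N(0, C_block) per haul ----
  int nblocks = block_start.size();
  std::vector<matrix<Type> > Cbi;
  std::vector<Type> ldCb;
  for (int bI = 0; bI < nblocks; bI++) {
    int s0 = block_start(bI), l = block_len(bI);
    matrix<Type> Cb(l, l);
    for (int i = 0; i < l; i++)
      for (int j = 0; j < l; j++) Cb(i, j) = C(s0 + i, s0 + j);
    Cbi.push_back(matrix<Type>(atomic::matinv(Cb)));
    ldCb.push_back(atomic::logdet(Cb));
  }
  for (int h = 0; h < haul_block.size(); h++) {
    int bI = haul_block(h), l = block_len(bI), o = eps_off(h);
    Type qe = Type(0);
    for (int i = 0; i < l; i++)
      for (int j = 0; j < l; j++) qe += eps(o + i) * Cbi[bI](i, j) * eps(o + j);
    nll += Type(0.5) * qe + Type(0.5) * ldCb[bI] +
           Type(0.5) * Type(l) * log2pi;
  }

  // ---- Poisson observations ----
  for (int r = 0; r < obs_count.size(); r++) {
    Type eta = mu(obs_class(r)) + sigma * xi(obs_class(r) + K * obs_cell(r)) +
               sigma_eps * eps(obs_eps(r));
    nll -= obs_count(r) * eta - exp(eta) - lgamma(obs_count(r) + Type(1));
  }

  REPORT(C);
  matrix<Type> S(M, M);
  for (int i = 0; i < M; i++)
    for (int j = 0; j < M; j++) S(i, j) = Qinv(i, j) / sqrt(d(i) * d(j));
  REPORT(S);

  ADREPORT(sigma);
  ADREPORT(sigma_eps);
  ADREPORT(delta);
  ADREPORT(a);
  ADREPORT(b);
  ADREPORT(c);
  ADREPORT(rho);
  ADREPORT(alpha);

  return nll;
}
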