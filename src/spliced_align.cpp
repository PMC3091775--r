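#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NEG = -100000000;

static inline int nt_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".seed_positions_cpp")]]
IntegerVector seed_positions_cpp(std::string subject, std::string query, int k) {
  // 0-based start positions in `subject` of any exact k-mer of `query`
  // (uppercase letters A-Z; windows containing other characters skipped)
  std::unordered_set<uint64_t> kmers;
  uint64_t base = 27;
  int nq = query.size(), ns = subject.size();
  for (int i = 0; i + k <= nq; ++i) {
    uint64_t code = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = query[i + j];
      if (c < 'A' || c > 'Z') { ok = false; break; }
      code = code * base + (c - 'A');
    }
    if (ok) kmers.insert(code);
  }
  std::vector<int> out;
  for (int i = 0; i + k <= ns; ++i) {
    uint64_t code = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = subject[i + j];
      if (c < 'A' || c > 'Z') { ok = false; break; }
      code = code * base + (c - 'A');
    }
    if (ok && kmers.count(code)) out.push_back(i);
  }
  return wrap(out);
}

// [[Rcpp::export(name = ".codon_nw_cpp")]]
List codon_nw_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_codon) {
  // global alignment with gaps constrained to codon boundaries;
  // column score = sum of per-nucleotide match/mismatch over the codon
  int na = a.size() / 3, nb = b.size() / 3;
  std::vector<std::vector<int>> S(na + 1, std::vector<int>(nb + 1, 0));
  std::vector<std::vector<unsigned char>> T(na + 1,
      std::vector<unsigned char>(nb + 1, 0)); // 1 diag, 2 up (gap in b), 3 left
  for (int i = 1; i <= na; ++i) { S[i][0] = -gap_codon * i; T[i][0] = 2; }
  for (int j = 1; j <= nb; ++j) { S[0][j] = -gap_codon * j; T[0][j] = 3; }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      int sc = 0;
      for (int p = 0; p < 3; ++p)
        sc += (a[3 * (i - 1) + p] == b[3 * (j - 1) + p]) ? match : mismatch;
      int d = S[i - 1][j - 1] + sc;
      int u = S[i - 1][j] - gap_codon;
      int l = S[i][j - 1] - gap_codon;
      if (d >= u && d >= l) { S[i][j] = d; T[i][j] = 1; }
      else if (u >= l) { S[i][j] = u; T[i][j] = 2; }
      else { S[i][j] = l; T[i][j] = 3; }
    }
  }
  std::string oa, ob;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    unsigned char t = T[i][j];
    if (t == 1) {
      oa = a.substr(3 * (i - 1), 3) + oa; ob = b.substr(3 * (j - 1), 3) + ob;
      --i; --j;
    } else if (t == 2) {
      oa = a.substr(3 * (i - 1), 3) + oa; ob = "---" + ob; --i;
    } else {
      oa = "---" + oa; ob = b.substr(3 * (j - 1), 3) + ob; --j;
    }
  }
  return List::create(_["score"] = S[na][nb], _["aligned_a"] = oa,
                      _["aligned_b"] = ob);
}

// Three-state local DP for spliced protein-to-genome alignment:
// codon match / codon-level gaps / intron (GT..AG bonus, length >= min_intron).
// Frameshift moves (2- or 4-nt pseudo-codons) let the alignment continue
// through single-nucleotide indels in decayed copies.
// [[Rcpp::export(name = ".spliced_align_cpp")]]
List spliced_align_cpp(std::string protein, std::string dna,
                       IntegerVector blosum, std::string code64,
                       int min_intron, int intron_open,
                       int donor_bonus, int acceptor_bonus,
                       int gap_codon, int fs_pen, int stop_score) {
  int m = protein.size(), n = dna.size();
  if (m < 1 || n < 3)
    return List::create(_["score"] = 0, _["exons"] = IntegerMatrix(0, 4),
                        _["introns"] = IntegerMatrix(0, 2));

  // residue score of protein[i-1] vs dna codon ending at 1-based position j
  std::vector<int> codon_of(n + 1, -1); // codon index for codon ending at j
  for (int j = 3; j <= n; ++j) {
    int a = nt_idx(dna[j - 3]), b = nt_idx(dna[j - 2]), c = nt_idx(dna[j - 1]);
    if (a >= 0 && b >= 0 && c >= 0) codon_of[j] = 16 * a + 4 * b + c;
  }
  auto sub = [&](int i, int j) -> int {
    int ci = codon_of[j];
    if (ci < 0) return -4;
    char aa = code64[ci];
    char p = protein[i - 1];
    if (aa == '*') return stop_score;
    if (p < 'A' || p > 'Z' || aa < 'A' || aa > 'Z') return -4;
    return blosum[(p - 'A') * 26 + (aa - 'A')];
  };
  auto donor = [&](int k1) -> int { // intron starts at 1-based k1
    return (k1 >= 1 && k1 + 1 <= n && dna[k1 - 1] == 'G' && dna[k1] == 'T')
      ? donor_bonus : 0;
  };
  auto acceptor = [&](int e) -> int { // intron ends at 1-based e
    return (e >= 2 && dna[e - 2] == 'A' && dna[e - 1] == 'G')
      ? acceptor_bonus : 0;
  };

  std::vector<std::vector<int>> M(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int>> J(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<unsigned char>> tbM(m + 1,
      std::vector<unsigned char>(n + 1, 0));
  std::vector<std::vector<unsigned char>> tbJ(m + 1,
      std::vector<unsigned char>(n + 1, 0)); // 0 extend, 1 enter

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // intron state (protein index unchanged while inside)
      int jx = NEG; unsigned char tj = 0;
      if (J[i][j - 1] > jx) { jx = J[i][j - 1]; tj = 0; }
      int k = j - min_intron;
      if (k >= 0 && M[i][k] > NEG) {
        int cand = M[i][k] - intron_open + donor(k + 1);
        if (cand > jx) { jx = cand; tj = 1; }
      }
      J[i][j] = jx; tbJ[i][j] = tj;

      if (j < 3) continue;
      int s = sub(i, j);
      int bestv = s; unsigned char tb = 0;             // fresh local start
      if (M[i - 1][j - 3] > NEG && M[i - 1][j - 3] + s > bestv) {
        bestv = M[i - 1][j - 3] + s; tb = 1;           // diagonal
      }
      if (j >= 2 && M[i - 1][j - 2] > NEG && M[i - 1][j - 2] - fs_pen > bestv) {
        bestv = M[i - 1][j - 2] - fs_pen; tb = 2;      // frameshift, 2 nt
      }
      if (j >= 4 && M[i - 1][j - 4] > NEG && M[i - 1][j - 4] - fs_pen > bestv) {
        bestv = M[i - 1][j - 4] - fs_pen; tb = 3;      // frameshift, 4 nt
      }
      if (M[i - 1][j] > NEG && M[i - 1][j] - gap_codon > bestv) {
        bestv = M[i - 1][j] - gap_codon; tb = 4;       // protein residue skipped
      }
      if (M[i][j - 3] > NEG && M[i][j - 3] - gap_codon > bestv) {
        bestv = M[i][j - 3] - gap_codon; tb = 5;       // extra codon in dna
      }
      if (J[i - 1][j - 3] > NEG &&
          J[i - 1][j - 3] + acceptor(j - 3) + s > bestv) {
        bestv = J[i - 1][j - 3] + acceptor(j - 3) + s; tb = 6; // close intron
      }
      M[i][j] = bestv; tbM[i][j] = tb;
      if (bestv > best) { best = bestv; bi = i; bj = j; }
    }
  }

  std::vector<std::array<int, 4>> exons;  // dna_start, dna_end (0-based ho), q_start, q_end
  std::vector<std::array<int, 2>> introns;
  if (bi > 0) {
    int i = bi, j = bj;
    int exon_dna_hi = j, exon_q_hi = i;
    bool done = false;
    while (!done) {
      unsigned char t = tbM[i][j];
      switch (t) {
      case 0: // fresh start: current codon opens the leftmost exon
        exons.push_back({j - 3, exon_dna_hi, i, exon_q_hi});
        done = true;
        break;
      case 1: --i; j -= 3; break;
      case 2: --i; j -= 2; break;
      case 3: --i; j -= 4; break;
      case 4: --i; break;
      case 5: j -= 3; break;
      case 6: { // intron closes just left of current codon
        exons.push_back({j - 3, exon_dna_hi, i, exon_q_hi});
        int e = j - 3;           // 1-based intron end
        int row = i - 1, col = e;
        while (tbJ[row][col] == 0) --col;
        int k = col - min_intron; // 1-based last exonic position before intron
        introns.push_back({k, e}); // 0-based half-open [k, e)
        i = row; j = k;
        exon_dna_hi = k; exon_q_hi = i;
        break;
      }
      }
    }
  }
  IntegerMatrix ex(exons.size(), 4), in(introns.size(), 2);
  for (size_t r = 0; r < exons.size(); ++r) {
    size_t rr = exons.size() - 1 - r; // emit left to right
    for (int c = 0; c < 4; ++c) ex(r, c) = exons[rr][c];
  }
  for (size_t r = 0; r < introns.size(); ++r) {
    size_t rr = introns.size() - 1 - r;
    in(r, 0) = introns[rr][0]; in(r, 1) = introns[rr][1];
  }
  return List::create(_["score"] = best, _["exons"] = ex, _["introns"] = in);
}
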