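// Seed-and-extend local alignment kernels: ungapped X-drop extension from
// exact word seeds, for nucleotide (fixed match/mismatch scores) and
// amino-acid (substitution matrix) comparisons.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int nt_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;  // N and friends seed nothing
  }
}

// encode all word-length windows of s as base-4 integers; -1 where invalid
static std::vector<long> nt_words(const std::string& s, int w) {
  int n = (int)s.size();
  std::vector<long> out;
  if (n < w) return out;
  out.assign(n - w + 1, -1);
  long mask = 1;
  for (int i = 0; i < w; ++i) mask *= 4;
  long code = 0;
  int valid = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = nt_code(s[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = (code * 4 + c) % mask;
    if (++valid >= w) out[i - w + 1] = code;
  }
  return out;
}

// Ungapped HSPs between query q and subject s from exact word seeds.
// Scoring: +match_score per identity, +mismatch_score (negative) otherwise;
// extension stops when the running score drops xdrop below the best seen.
// Returns a matrix with rows (qstart, qend, sstart, send, score); 0-based
// half-open on both sequences. Seeds falling inside an HSP already
// extended on the same diagonal are skipped.
// [[Rcpp::export]]
IntegerMatrix nt_hsps_cpp(std::string q, std::string s, int word,
                          int match_score, int mismatch_score,
                          int xdrop, int min_score) {
  std::vector<long> qw = nt_words(q, word);
  std::vector<long> sw = nt_words(s, word);
  std::unordered_map<long, std::vector<int> > idx;
  idx.reserve(sw.size() * 2 + 1);
  for (int j = 0; j < (int)sw.size(); ++j)
    if (sw[j] >= 0) idx[sw[j]].push_back(j);

  std::unordered_map<long, int> diag_reach;  // diagonal -> q end reached
  std::vector<int> rows;
  int nq = (int)q.size(), ns = (int)s.size();

  for (int i = 0; i < (int)qw.size(); ++i) {
    if (qw[i] < 0) continue;
    std::unordered_map<long, std::vector<int> >::iterator it = idx.find(qw[i]);
    if (it == idx.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t) {
      int j = it->second[t];
      long diag = (long)i - j + ns;  // shift to keep keys positive-ish
      std::unordered_map<long, int>::iterator dr = diag_reach.find(diag);
      if (dr != diag_reach.end() && i < dr->second) continue;
      // seed core
      int score = word * match_score;
      // extend right from (i + word, j + word)
      int best_r = 0, run = 0;
      int qi = i + word, sj = j + word, qend = i + word;
      while (qi < nq && sj < ns) {
        run += (q[qi] == s[sj] && nt_code(q[qi]) >= 0) ? match_score : mismatch_score;
        if (run > best_r) { best_r = run; qend = qi + 1; }
        if (best_r - run >= xdrop) break;
        ++qi; ++sj;
      }
      // extend left from (i - 1, j - 1)
      int best_l = 0; run = 0;
      qi = i - 1; sj = j - 1;
      int qstart = i;
      while (qi >= 0 && sj >= 0) {
        run += (q[qi] == s[sj] && nt_code(q[qi]) >= 0) ? match_score : mismatch_score;
        if (run > best_l) { best_l = run; qstart = qi; }
        if (best_l - run >= xdrop) break;
        --qi; --sj;
      }
      score += best_r + best_l;
      diag_reach[diag] = qend;
      if (score >= min_score) {
        int sstart = j - (i - qstart);
        int send = sstart + (qend - qstart);
        rows.push_back(qstart); rows.push_back(qend);
        rows.push_back(sstart); rows.push_back(send);
        rows.push_back(score);
      }
    }
  }
  int nr = (int)rows.size() / 5;
  IntegerMatrix out(nr, 5);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 5; ++c) out(r, c) = rows[r * 5 + c];
  colnames(out) = CharacterVector::create("qstart", "qend", "sstart", "send", "score");
  return out;
}

// Batched nucleotide homology: one subject (the phage) is indexed once in
// a direct-address table over all 4^word codes; every query (host strand)
// is streamed against it. Queries sharing a group id (the two strands of
// one host) have their qualifying subject intervals unioned together.
// Returns one row per group: (union_len, n_hsps, best_score).
// [[Rcpp::export]]
NumericMatrix nt_homology_groups_cpp(std::string subject,
                                     CharacterVector queries,
                                     IntegerVector group,
                                     int word, int match_score,
                                     int mismatch_score, int xdrop,
                                     int min_score) {
  std::vector<long> sw = nt_words(subject, word);
  long table_size = 1;
  for (int i = 0; i < word; ++i) table_size *= 4;
  // chained direct-address index: head[code] -> first window, nxt -> next
  std::vector<int> head(table_size, -1), nxt(sw.size(), -1);
  for (int j = (int)sw.size() - 1; j >= 0; --j) {
    if (sw[j] >= 0) { nxt[j] = head[sw[j]]; head[sw[j]] = j; }
  }
  int ngroup = 0;
  for (int g = 0; g < group.size(); ++g) ngroup = std::max(ngroup, group[g] + 1);
  std::vector<std::vector<std::pair<int, int> > > ivals(ngroup);
  std::vector<double> best(ngroup, 0.0);
  std::vector<int> nhsp(ngroup, 0);
  int ns = (int)subject.size();

  for (int qI = 0; qI < queries.size(); ++qI) {
    std::string q = as<std::string>(queries[qI]);
    int grp = group[qI];
    std::vector<long> qw = nt_words(q, word);
    int nq = (int)q.size();
    std::unordered_map<long, int> diag_reach;
    for (int i = 0; i < (int)qw.size(); ++i) {
      if (qw[i] < 0) continue;
      for (int j = head[qw[i]]; j >= 0; j = nxt[j]) {
        long diag = (long)i - j + ns;
        std::unordered_map<long, int>::iterator dr = diag_reach.find(diag);
        if (dr != diag_reach.end() && i < dr->second) continue;
        int score = word * match_score;
        int best_r = 0, run = 0;
        int qi = i + word, sj = j + word, qend = i + word;
        while (qi < nq && sj < ns) {
          run += (q[qi] == subject[sj] && nt_code(q[qi]) >= 0)
                   ? match_score : mismatch_score;
          if (run > best_r) { best_r = run; qend = qi + 1; }
          if (best_r - run >= xdrop) break;
          ++qi; ++sj;
        }
        int best_l = 0; run = 0;
        qi = i - 1; sj = j - 1;
        int qstart = i;
        while (qi >= 0 && sj >= 0) {
          run += (q[qi] == subject[sj] && nt_code(q[qi]) >= 0)
                   ? match_score : mismatch_score;
          if (run > best_l) { best_l = run; qstart = qi; }
          if (best_l - run >= xdrop) break;
          --qi; --sj;
        }
        score += best_r + best_l;
        diag_reach[diag] = qend;
        if (score >= min_score) {
          int sstart = j - (i - qstart);
          ivals[grp].push_back(std::make_pair(sstart, sstart + (qend - qstart)));
          nhsp[grp] += 1;
          if (score > best[grp]) best[grp] = score;
        }
      }
    }
  }
  NumericMatrix out(ngroup, 3);
  for (int g = 0; g < ngroup; ++g) {
    std::vector<std::pair<int, int> >& v = ivals[g];
    std::sort(v.begin(), v.end());
    long total = 0;
    if (!v.empty()) {
      int cur_s = v[0].first, cur_e = v[0].second;
      for (size_t t = 1; t < v.size(); ++t) {
        if (v[t].first > cur_e) {
          total += cur_e - cur_s;
          cur_s = v[t].first; cur_e = v[t].second;
        } else if (v[t].second > cur_e) {
          cur_e = v[t].second;
        }
      }
      total += cur_e - cur_s;
    }
    out(g, 0) = (double)total;
    out(g, 1) = nhsp[g];
    out(g, 2) = best[g];
  }
  colnames(out) = CharacterVector::create("union_len", "n_hsps", "best_score");
  return out;
}

// Best ungapped seed-extended score of each query peptide against a set of
// subject peptides. Seeds are exact amino-acid words of length `word`;
// extension scores come from `submat` (rows/cols ordered as `alphabet`).
// Returns, per query, the best score over all subjects (0 when no seed).
// [[Rcpp::export]]
NumericVector aa_best_scores_cpp(CharacterVector queries,
                                 CharacterVector subjects,
                                 IntegerMatrix submat,
                                 std::string alphabet,
                                 int word, int xdrop) {
  int A = (int)alphabet.size();
  std::vector<int> lut(256, -1);
  for (int a = 0; a < A; ++a) lut[(unsigned char)alphabet[a]] = a;

  // index subject words -> (subject, position)
  std::unordered_map<long, std::vector<std::pair<int, int> > > idx;
  std::vector<std::string> subs(subjects.size());
  for (int sI = 0; sI < subjects.size(); ++sI) {
    subs[sI] = as<std::string>(subjects[sI]);
    const std::string& s = subs[sI];
    for (int j = 0; j + word <= (int)s.size(); ++j) {
      long code = 0; bool ok = true;
      for (int t = 0; t < word; ++t) {
        int c = lut[(unsigned char)s[j + t]];
        if (c < 0) { ok = false; break; }
        code = code * A + c;
      }
      if (ok) idx[code].push_back(std::make_pair(sI, j));
    }
  }

  NumericVector best(queries.size());
  for (int qI = 0; qI < queries.size(); ++qI) {
    std::string qs = as<std::string>(queries[qI]);
    int nq = (int)qs.size();
    double bq = 0;
    std::unordered_map<long, int> diag_reach;  // (subject, diag) packed -> q reach
    for (int i = 0; i + word <= nq; ++i) {
      long code = 0; bool ok = true;
      for (int t = 0; t < word; ++t) {
        int c = lut[(unsigned char)qs[i + t]];
        if (c < 0) { ok = false; break; }
        code = code * A + c;
      }
      if (!ok) continue;
      std::unordered_map<long, std::vector<std::pair<int, int> > >::iterator it =
        idx.find(code);
      if (it == idx.end()) continue;
      for (size_t t = 0; t < it->second.size(); ++t) {
        int sI = it->second[t].first;
        int j = it->second[t].second;
        const std::string& s = subs[sI];
        int ns = (int)s.size();
        long key = (long)sI * 2000003L + ((long)i - j + ns);
        std::unordered_map<long, int>::iterator dr = diag_reach.find(key);
        if (dr != diag_reach.end() && i < dr->second) continue;
        int score = 0;
        for (int tt = 0; tt < word; ++tt) {
          int a = lut[(unsigned char)qs[i + tt]], b = lut[(unsigned char)s[j + tt]];
          score += submat(a, b);
        }
        int run = 0, best_r = 0, qi = i + word, sj = j + word, qend = i + word;
        while (qi < nq && sj < ns) {
          int a = lut[(unsigned char)qs[qi]], b = lut[(unsigned char)s[sj]];
          if (a < 0 || b < 0) break;
          run += submat(a, b);
          if (run > best_r) { best_r = run; qend = qi + 1; }
          if (best_r - run >= xdrop) break;
          ++qi; ++sj;
        }
        run = 0; int best_l = 0;
        qi = i - 1; sj = j - 1;
        while (qi >= 0 && sj >= 0) {
          int a = lut[(unsigned char)qs[qi]], b = lut[(unsigned char)s[sj]];
          if (a < 0 || b < 0) break;
          run += submat(a, b);
          if (run > best_l) best_l = run;
          if (best_l - run >= xdrop) break;
          --qi; --sj;
        }
        score += best_r + best_l;
        diag_reach[key] = qend;
        if (score > bq) bq = score;
      }
    }
    best[qI] = bq;
  }
  return best;
}
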