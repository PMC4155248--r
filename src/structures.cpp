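#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

// Bases are encoded A=0, C=1, G=2, U=3 (see .encode_bases on the R side).
static inline bool can_pair(int a, int b) {
    // Watson-Crick (A-U, G-C) and wobble (G-U), either orientation.
    switch (a * 4 + b) {
    case 0 * 4 + 3: case 3 * 4 + 0:        // A-U / U-A
    case 2 * 4 + 1: case 1 * 4 + 2:        // G-C / C-G
    case 2 * 4 + 3: case 3 * 4 + 2:        // G-U / U-G
        return true;
    default:
        return false;
    }
}

// Interval DP counting all nested structures; doubles overflow gracefully
// to +Inf which the R caller treats as "over any cap".
// [[Rcpp::export]]
double cpp_count_structures(IntegerVector seq, int min_loop) {
    int n = seq.size();
    if (n == 0) return 1.0;
    std::vector<double> N((size_t)n * n, 0.0);
    // N[i + n*j] = number of structures on [i, j]; empty interval = 1.
    for (int j = 0; j < n; ++j) {
        for (int i = j; i >= 0; --i) {
            double tot = (i + 1 <= j) ? N[(i + 1) + (size_t)n * j] : 1.0;
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                double left = (i + 1 <= k - 1) ? N[(i + 1) + (size_t)n * (k - 1)] : 1.0;
                double right = (k + 1 <= j) ? N[(k + 1) + (size_t)n * j] : 1.0;
                tot += left * right;
            }
            N[i + (size_t)n * j] = tot;
        }
    }
    return N[0 + (size_t)n * (n - 1)];
}

struct Enumerator {
    const IntegerVector &seq;
    int n, min_loop;
    std::vector<char> db;
    std::vector<std::pair<int, int> > todo;  // stack of open intervals
    std::vector<std::string> out;
    Enumerator(const IntegerVector &s, int ml)
        : seq(s), n(s.size()), min_loop(ml), db(s.size(), '.') {}
    void rec() {
        if (todo.empty()) {
            out.push_back(std::string(db.begin(), db.end()));
            return;
        }
        std::pair<int, int> iv = todo.back();
        todo.pop_back();
        int i = iv.first, j = iv.second;
        if (i > j) {
            rec();
        } else {
            // i unpaired
            if (i + 1 <= j) todo.push_back(std::make_pair(i + 1, j));
            rec();
            if (i + 1 <= j) todo.pop_back();
            // i paired with k
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                db[i] = '(';
                db[k] = ')';
                size_t pushed = 0;
                if (k + 1 <= j) { todo.push_back(std::make_pair(k + 1, j)); ++pushed; }
                if (i + 1 <= k - 1) { todo.push_back(std::make_pair(i + 1, k - 1)); ++pushed; }
                rec();
                while (pushed--) todo.pop_back();
                db[i] = '.';
                db[k] = '.';
            }
        }
        todo.push_back(iv);
    }
};

// All nested structures of `seq` as dot-bracket strings (unsorted).
// [[Rcpp::export]]
CharacterVector cpp_enumerate_structures(IntegerVector seq, int min_loop) {
    Enumerator en(seq, min_loop);
    if (seq.size() > 0) en.todo.push_back(std::make_pair(0, seq.size() - 1));
    en.rec();
    if (!en.todo.empty()) en.todo.pop_back();
    return wrap(en.out);
}

static std::vector<int> pairing_of(const std::string &db) {
    std::vector<int> p(db.size(), -1), stack;
    for (size_t i = 0; i < db.size(); ++i) {
        if (db[i] == '(') {
            stack.push_back((int)i);
        } else if (db[i] == ')') {
            if (stack.empty()) stop("unbalanced dot-bracket");
            p[i] = stack.back();
            p[stack.back()] = (int)i;
            stack.pop_back();
        }
    }
    if (!stack.empty()) stop("unbalanced dot-bracket");
    return p;
}

static void neighbor_strings(const std::string &db, const IntegerVector &seq,
                             int min_loop, std::vector<std::string> &out) {
    int n = (int)db.size();
    std::vector<int> p = pairing_of(db);
    // removals
    for (int i = 0; i < n; ++i) {
        if (p[i] > i) {
            std::string s = db;
            s[i] = '.';
            s[p[i]] = '.';
            out.push_back(s);
        }
    }
    // additions: (i, j) admissible, both unpaired, non-crossing
    for (int i = 0; i < n; ++i) {
        if (p[i] >= 0) continue;
        for (int j = i + min_loop + 1; j < n; ++j) {
            if (p[j] >= 0 || !can_pair(seq[i], seq[j])) continue;
            bool ok = true;
            for (int k = 0; k < n && ok; ++k) {
                int l = p[k];
                if (l <= k) continue;
                if ((k < i && i < l && l < j) || (i < k && k < j && j < l))
                    ok = false;
            }
            if (ok) {
                std::string s = db;
                s[i] = '(';
                s[j] = ')';
                out.push_back(s);
            }
        }
    }
}

// Single-structure move set: all structures differing by one base pair.
// [[Rcpp::export]]
CharacterVector cpp_neighbors(std::string db, IntegerVector seq, int min_loop) {
    std::vector<std::string> out;
    neighbor_strings(db, seq, min_loop, out);
    std::sort(out.begin(), out.end());
    return wrap(out);
}

// Adjacency lists (1-based indices) over an enumerated state set.
// Neighbors absent from `keys` (energy-bounded sets) are dropped.
// [[Rcpp::export]]
List cpp_adjacency(CharacterVector keys, IntegerVector seq, int min_loop) {
    int m = keys.size();
    std::unordered_map<std::string, int> lut;
    lut.reserve((size_t)m * 2);
    for (int i = 0; i < m; ++i) lut[std::string(keys[i])] = i;
    List adj(m);
    std::vector<std::string> nb;
    for (int i = 0; i < m; ++i) {
        nb.clear();
        neighbor_strings(std::string(keys[i]), seq, min_loop, nb);
        std::vector<int> ids;
        ids.reserve(nb.size());
        for (size_t k = 0; k < nb.size(); ++k) {
            std::unordered_map<std::string, int>::iterator it = lut.find(nb[k]);
            if (it != lut.end()) ids.push_back(it->second + 1);
        }
        std::sort(ids.begin(), ids.end());
        adj[i] = IntegerVector(ids.begin(), ids.end());
    }
    return adj;
}

// Additive base-pair energies: E(s) = sum over pairs of pair_e[type],
// pair_e = c(GC, AU, GU) energies.
// [[Rcpp::export]]
NumericVector cpp_simple_energy(CharacterVector keys, IntegerVector seq,
                                NumericVector pair_e) {
    int m = keys.size();
    NumericVector e(m);
    for (int i = 0; i < m; ++i) {
        std::string db = std::string(keys[i]);
        std::vector<int> p = pairing_of(db);
        double tot = 0.0;
        for (size_t k = 0; k < p.size(); ++k) {
            if (p[k] <= (int)k) continue;
            int a = seq[k], b = seq[p[k]];
            if ((a == 2 && b == 1) || (a == 1 && b == 2)) tot += pair_e[0];
            else if ((a == 0 && b == 3) || (a == 3 && b == 0)) tot += pair_e[1];
            else if ((a == 2 && b == 3) || (a == 3 && b == 2)) tot += pair_e[2];
            else stop("inadmissible pair in structure");
        }
        e[i] = tot;
    }
    return e;
}

// Byte-wise (C locale) string comparison, elementwise a < b.
// [[Rcpp::export]]
LogicalVector cpp_str_lt(CharacterVector a, CharacterVector b) {
    int n = std::max(a.size(), b.size());
    LogicalVector out(n);
    for (int i = 0; i < n; ++i) {
        const char *x = CHAR(STRING_ELT(a, i % a.size()));
        const char *y = CHAR(STRING_ELT(b, i % b.size()));
        out[i] = std::strcmp(x, y) < 0;
    }
    return out;
}
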