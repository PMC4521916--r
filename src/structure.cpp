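#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// from treedist.cpp
int tree_edit_distance_cpp(IntegerVector labels1, IntegerVector lld1,
                           IntegerVector labels2, IntegerVector lld2);

// label codes match the R-side SHAPIRO_LABELS = c(R,E,S,H,I,B,M)
enum ShapLabel { LR = 1, LE = 2, LS = 3, LH = 4, LI = 5, LB = 6, LM = 7 };

// 1-based pairing table from a dot-bracket string; 0 = unpaired.
// Returns false on imbalance (err_idx set 0-based).
static bool pair_table(const std::string& db, std::vector<int>& pt,
                       int& err_idx) {
    const int n = (int) db.size();
    pt.assign(n + 1, 0);
    std::vector<int> stack;
    for (int k = 1; k <= n; ++k) {
        char c = db[k - 1];
        if (c == '(') stack.push_back(k);
        else if (c == ')') {
            if (stack.empty()) { err_idx = k - 1; return false; }
            pt[stack.back()] = k;
            pt[k] = stack.back();
            stack.pop_back();
        } else if (c != '.') { err_idx = k - 1; return false; }
    }
    if (!stack.empty()) { err_idx = stack.front() - 1; return false; }
    return true;
}

// [[Rcpp::export(name = ".dotbracket_pairs_cpp")]]
List dotbracket_pairs_cpp(std::string db) {
    std::vector<int> pt;
    int err = -1;
    if (!pair_table(db, pt, err))
        return List::create(_["ok"] = false, _["index"] = err);
    std::vector<int> pi, pj;
    for (int i = 1; i <= (int) db.size(); ++i)
        if (pt[i] > i) { pi.push_back(i - 1); pj.push_back(pt[i] - 1); }
    IntegerMatrix m(pi.size(), 2);
    for (size_t r = 0; r < pi.size(); ++r) {
        m(r, 0) = pi[r]; m(r, 1) = pj[r];
    }
    return List::create(_["ok"] = true, _["pairs"] = m);
}

struct ShapTree {
    std::vector<int> lab, par, lo, hi;  // preorder; spans 0-based half-open
    int add(int label, int parent, int l, int h) {
        lab.push_back(label); par.push_back(parent);
        lo.push_back(l); hi.push_back(h);
        return (int) lab.size();
    }
};

static void build_stem(const std::vector<int>& pt, int i, int parent,
                       ShapTree& t) {
    int j = pt[i], i2 = i, j2 = j;
    while (i2 + 1 < j2 - 1 && pt[i2 + 1] == j2 - 1) { ++i2; --j2; }
    int sid = t.add(LS, parent, i - 1, j);
    int lo = i2 + 1, hi = j2 - 1;
    std::vector<int> starts;
    std::vector<int> gaps;
    int gap = 0, pos = lo;
    while (pos <= hi) {
        if (pt[pos] > pos) {
            starts.push_back(pos);
            gaps.push_back(gap); gap = 0;
            pos = pt[pos] + 1;
        } else { ++gap; ++pos; }
    }
    gaps.push_back(gap);
    int k = (int) starts.size();
    int label = (k == 0) ? LH
              : (k == 1) ? ((gaps[0] > 0 && gaps[1] > 0) ? LI : LB)
              : LM;
    int lid = t.add(label, sid, lo - 1, hi);
    for (int st : starts) build_stem(pt, st, lid, t);
}

static ShapTree shapiro_decompose(const std::vector<int>& pt, int n) {
    ShapTree t;
    int rid = t.add(LR, 0, 0, n);
    int pos = 1;
    while (pos <= n) {
        if (pt[pos] > pos) {
            build_stem(pt, pos, rid, t);
            pos = pt[pos] + 1;
        } else {
            int e = pos;
            while (e <= n && pt[e] == 0) ++e;
            t.add(LE, rid, pos - 1, e - 1);
            pos = e;
        }
    }
    return t;
}

// [[Rcpp::export(name = ".shapiro_tree_cpp")]]
List shapiro_tree_cpp(std::string db) {
    std::vector<int> pt;
    int err = -1;
    if (!pair_table(db, pt, err))
        stop("invalid dot-bracket at index %d", err);
    ShapTree t = shapiro_decompose(pt, (int) db.size());
    return List::create(_["labels"] = wrap(t.lab), _["parent"] = wrap(t.par),
                        _["lo"] = wrap(t.lo), _["hi"] = wrap(t.hi));
}

// postorder labels + leftmost-leaf indices for Zhang-Shasha
static void postorder_of(const ShapTree& t, std::vector<int>& plab,
                         std::vector<int>& lld) {
    int n = (int) t.lab.size();
    std::vector< std::vector<int> > children(n + 1);
    for (int i = 2; i <= n; ++i) children[t.par[i - 1]].push_back(i);
    std::vector<int> post;
    std::function<void(int)> visit = [&](int i) {
        for (int c : children[i]) visit(c);
        post.push_back(i);
    };
    visit(1);
    std::vector<int> postpos(n + 1, 0);
    for (int p = 0; p < n; ++p) postpos[post[p]] = p + 1;
    plab.resize(n); lld.resize(n);
    for (int p = 0; p < n; ++p) {
        int i = post[p];
        plab[p] = t.lab[i - 1];
        int j = i;
        while (!children[j].empty()) j = children[j][0];
        lld[p] = postpos[j];
    }
}

// [[Rcpp::export(name = ".shapiro_post_cpp")]]
List shapiro_post_cpp(std::string db) {
    std::vector<int> pt;
    int err = -1;
    if (!pair_table(db, pt, err))
        stop("invalid dot-bracket at index %d", err);
    ShapTree t = shapiro_decompose(pt, (int) db.size());
    std::vector<int> plab, lld;
    postorder_of(t, plab, lld);
    return List::create(_["labels"] = wrap(plab), _["lld"] = wrap(lld));
}

// base-pair distance (symmetric difference) between two equal-length
// dot-bracket strings, plus the Shapiro tree edit distance of the candidate
// against a precomputed target postorder.  The annealer's hot path.
// [[Rcpp::export(name = ".structure_scores_cpp")]]
IntegerVector structure_scores_cpp(std::string cand_db,
                                   IntegerMatrix target_pairs,
                                   IntegerVector target_plab,
                                   IntegerVector target_lld) {
    const int n = (int) cand_db.size();
    std::vector<int> pt;
    int err = -1;
    if (!pair_table(cand_db, pt, err))
        stop("invalid dot-bracket at index %d", err);

    // symmetric difference on encoded pairs
    std::vector<long> ca, tb;
    for (int i = 1; i <= n; ++i)
        if (pt[i] > i) ca.push_back((long) (i - 1) * n + (pt[i] - 1));
    for (int r = 0; r < target_pairs.nrow(); ++r)
        tb.push_back((long) target_pairs(r, 0) * n + target_pairs(r, 1));
    std::sort(ca.begin(), ca.end());
    std::sort(tb.begin(), tb.end());
    std::vector<long> inter;
    std::set_intersection(ca.begin(), ca.end(), tb.begin(), tb.end(),
                          std::back_inserter(inter));
    int bp = (int) (ca.size() + tb.size() - 2 * inter.size());

    ShapTree t = shapiro_decompose(pt, n);
    std::vector<int> plab, lld;
    postorder_of(t, plab, lld);
    int shap = tree_edit_distance_cpp(wrap(plab), wrap(lld),
                                      target_plab, target_lld);
    return IntegerVector::create(bp, shap);
}
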