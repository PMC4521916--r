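#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Zhang-Shasha ordered labelled tree edit distance with unit insert, delete
// and relabel costs.  Trees are passed as postorder label codes plus, for
// each node, the postorder index (1-based) of the leftmost leaf of its
// subtree.
// [[Rcpp::export(name = ".tree_edit_distance_cpp")]]
int tree_edit_distance_cpp(IntegerVector labels1, IntegerVector lld1,
                           IntegerVector labels2, IntegerVector lld2) {
    const int n1 = labels1.size(), n2 = labels2.size();
    if (n1 == 0) return n2;
    if (n2 == 0) return n1;

    // LR keyroots: nodes with no proper ancestor sharing the same leftmost leaf
    std::vector<int> kr1, kr2;
    for (int k = 1; k <= n1; ++k) {
        bool key = true;
        for (int kp = k + 1; kp <= n1; ++kp)
            if (lld1[kp - 1] == lld1[k - 1]) { key = false; break; }
        if (key) kr1.push_back(k);
    }
    for (int k = 1; k <= n2; ++k) {
        bool key = true;
        for (int kp = k + 1; kp <= n2; ++kp)
            if (lld2[kp - 1] == lld2[k - 1]) { key = false; break; }
        if (key) kr2.push_back(k);
    }

    std::vector< std::vector<int> > td(n1 + 1, std::vector<int>(n2 + 1, 0));
    std::vector< std::vector<int> > fd(n1 + 2, std::vector<int>(n2 + 2, 0));

    for (size_t x = 0; x < kr1.size(); ++x) {
        int i = kr1[x];
        int li = lld1[i - 1];
        for (size_t y = 0; y < kr2.size(); ++y) {
            int j = kr2[y];
            int lj = lld2[j - 1];

            fd[li - 1][lj - 1] = 0;
            for (int di = li; di <= i; ++di)
                fd[di][lj - 1] = fd[di - 1][lj - 1] + 1;
            for (int dj = lj; dj <= j; ++dj)
                fd[li - 1][dj] = fd[li - 1][dj - 1] + 1;

            for (int di = li; di <= i; ++di) {
                for (int dj = lj; dj <= j; ++dj) {
                    if (lld1[di - 1] == li && lld2[dj - 1] == lj) {
                        int rel = (labels1[di - 1] == labels2[dj - 1]) ? 0 : 1;
                        fd[di][dj] = std::min(std::min(
                            fd[di - 1][dj] + 1,
                            fd[di][dj - 1] + 1),
                            fd[di - 1][dj - 1] + rel);
                        td[di][dj] = fd[di][dj];
                    } else {
                        fd[di][dj] = std::min(std::min(
                            fd[di - 1][dj] + 1,
                            fd[di][dj - 1] + 1),
                            fd[lld1[di - 1] - 1][lld2[dj - 1] - 1] + td[di][dj]);
                    }
                }
            }
        }
    }
    return td[n1][n2];
}
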