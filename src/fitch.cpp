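#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// State-set codes for binary characters: 1 = {0}, 2 = {1}, 3 = {0,1}.
//
// The downpass implements Hartigan's rule: at a node with k children, a state
// is retained if it occurs in a maximal number of child state sets, and
// k - max_count steps are added.  For two states on a bifurcating node this is
// exactly the Fitch rule (intersection if non-empty, else union plus one step),
// and it remains exact on multifurcating nodes, so consensus trees and the
// basal trichotomy of unrooted trees are scored correctly.

static void postorderNodes(const IntegerMatrix &edge, int maxNode,
                           std::vector<int> &order, std::vector<std::vector<int> > &kids) {
    int nE = edge.nrow();
    kids.assign(maxNode + 1, std::vector<int>());
    std::vector<char> isChild(maxNode + 1, 0);
    for (int e = 0; e < nE; ++e) {
        kids[edge(e, 0)].push_back(edge(e, 1));
        isChild[edge(e, 1)] = 1;
    }
    int root = -1;
    for (int e = 0; e < nE; ++e)
        if (!isChild[edge(e, 0)]) { root = edge(e, 0); break; }
    if (root < 0) stop("edge matrix has no root (cycle?)");
    // iterative DFS; reversed preorder of a DFS visiting children in order is
    // a valid postorder for step accumulation (children before parents)
    order.clear();
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        order.push_back(v);
        for (size_t i = 0; i < kids[v].size(); ++i) stack.push_back(kids[v][i]);
    }
    std::reverse(order.begin(), order.end());
}

static void fitchOne(const IntegerMatrix &edge, int nTip,
                     const IntegerMatrix &tipCodes, IntegerVector &steps) {
    int nChar = tipCodes.nrow();
    int maxNode = 0, nE = edge.nrow();
    for (int e = 0; e < nE; ++e) {
        if (edge(e, 0) > maxNode) maxNode = edge(e, 0);
        if (edge(e, 1) > maxNode) maxNode = edge(e, 1);
    }
    std::vector<int> order;
    std::vector<std::vector<int> > kids;
    postorderNodes(edge, maxNode, order, kids);

    std::vector<unsigned char> sets((size_t)(maxNode + 1) * nChar, 0);
    for (size_t oi = 0; oi < order.size(); ++oi) {
        int v = order[oi];
        unsigned char *sv = &sets[(size_t)v * nChar];
        if (v <= nTip) {
            for (int c = 0; c < nChar; ++c) sv[c] = (unsigned char) tipCodes(c, v - 1);
        } else {
            const std::vector<int> &kv = kids[v];
            int k = (int) kv.size();
            for (int c = 0; c < nChar; ++c) {
                int cnt0 = 0, cnt1 = 0;
                for (int j = 0; j < k; ++j) {
                    unsigned char s = sets[(size_t)kv[j] * nChar + c];
                    cnt0 += s & 1;
                    cnt1 += (s >> 1) & 1;
                }
                int mx = cnt0 > cnt1 ? cnt0 : cnt1;
                steps[c] += k - mx;
                sv[c] = (unsigned char)((cnt0 == mx ? 1 : 0) | (cnt1 == mx ? 2 : 0));
            }
        }
    }
}

// [[Rcpp::export(name = ".fitchStepsC")]]
IntegerVector fitchStepsC(IntegerMatrix edge, int nTip, IntegerMatrix tipCodes) {
    IntegerVector steps(tipCodes.nrow());
    fitchOne(edge, nTip, tipCodes, steps);
    return steps;
}

// Total lengths for a list of edge matrices over the same tips (used by the
// exhaustive search, TBR sweeps and random-tree length distributions).
// [[Rcpp::export(name = ".fitchTotalManyC")]]
IntegerVector fitchTotalManyC(List edges, int nTip, IntegerMatrix tipCodes) {
    int n = edges.size();
    int nChar = tipCodes.nrow();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        IntegerMatrix edge = edges[i];
        IntegerVector steps(nChar);
        fitchOne(edge, nTip, tipCodes, steps);
        long tot = 0;
        for (int c = 0; c < nChar; ++c) tot += steps[c];
        out[i] = (int) tot;
    }
    return out;
}
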