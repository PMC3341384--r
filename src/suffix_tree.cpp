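#include <Rcpp.h>
#include <map>
#include <vector>
#include <climits>

using namespace Rcpp;

// Ukkonen's online construction of a suffix tree over an integer token
// stream.  Rows of the stamped transition matrix are concatenated, each
// followed by a unique terminator token; because terminators occur exactly
// once, no internal (branching) node path ever crosses a row boundary, so
// the tree behaves as a generalized suffix tree of the row strings.
//
// Children are held in std::map keyed by token id, giving a deterministic
// DFS order (ascending token).

namespace {

struct STBuilder {
    const std::vector<int> &txt;   // 0-based token ids
    int n;

    std::vector<int> start_;       // edge start position (0-based, into txt)
    std::vector<int> end_;         // edge end position, inclusive; INT_MAX for leaves
    std::vector<int> slink_;
    std::vector< std::map<int, int> > ch_;

    int root;
    int activeNode, activeEdge, activeLength, remaining, lastNewNode;

    explicit STBuilder(const std::vector<int> &t)
        : txt(t), n((int) t.size()) {
        root = newNode(-1, -1);
        activeNode = root;
        activeEdge = 0;
        activeLength = 0;
        remaining = 0;
        lastNewNode = -1;
    }

    int newNode(int s, int e) {
        start_.push_back(s);
        end_.push_back(e);
        slink_.push_back(0);           // root index (set after root exists)
        ch_.push_back(std::map<int, int>());
        return (int) start_.size() - 1;
    }

    int edgeLen(int v, int pos) const {
        return std::min(end_[v], pos) - start_[v] + 1;
    }

    bool walkDown(int v, int pos) {
        int el = edgeLen(v, pos);
        if (activeLength >= el) {
            activeEdge += el;
            activeLength -= el;
            activeNode = v;
            return true;
        }
        return false;
    }

    void extend(int pos) {
        remaining++;
        lastNewNode = -1;
        while (remaining > 0) {
            if (activeLength == 0) activeEdge = pos;
            std::map<int, int>::iterator it =
                ch_[activeNode].find(txt[activeEdge]);
            if (it == ch_[activeNode].end()) {
                int leaf = newNode(pos, INT_MAX);
                ch_[activeNode][txt[activeEdge]] = leaf;
                if (lastNewNode != -1) {
                    slink_[lastNewNode] = activeNode;
                    lastNewNode = -1;
                }
            } else {
                int nxt = it->second;
                if (walkDown(nxt, pos)) continue;
                if (txt[start_[nxt] + activeLength] == txt[pos]) {
                    if (lastNewNode != -1 && activeNode != root) {
                        slink_[lastNewNode] = activeNode;
                        lastNewNode = -1;
                    }
                    activeLength++;
                    break;
                }
                int split = newNode(start_[nxt], start_[nxt] + activeLength - 1);
                ch_[activeNode][txt[activeEdge]] = split;
                int leaf = newNode(pos, INT_MAX);
                ch_[split][txt[pos]] = leaf;
                start_[nxt] += activeLength;
                ch_[split][txt[start_[nxt]]] = nxt;
                if (lastNewNode != -1) slink_[lastNewNode] = split;
                lastNewNode = split;
            }
            remaining--;
            if (activeNode == root && activeLength > 0) {
                activeLength--;
                activeEdge = pos - remaining + 1;
            } else if (activeNode != root) {
                activeNode = slink_[activeNode];
            }
        }
    }

    void build() {
        for (int i = 0; i < n; ++i) extend(i);
    }
};

} // namespace

// Builds the suffix tree over `tokens` (positive integer ids; the final
// token of each row must be a terminator unique in the whole stream) and
// returns a flat node table plus a DFS leaf ordering, everything 1-based
// for the R side:
//   start, end       edge label positions into the token stream (root: 0,0);
//                    leaf edges clipped to n
//   slink            suffix-link target node id (0 = none/unset, root has 0)
//   isLeaf           logical
//   tokenDepth       path length in tokens from the root
//   firstPos         text position of the first token of the node's path
//                    (0 for root)
//   leafLo, leafHi   range of DFS-ordered leaves under the node
//   leafSuffix       for DFS leaf k, the 1-based start position of its suffix
//   edgeParent/edgeChild  all tree edges in DFS discovery order
// [[Rcpp::export(name = ".cpp_build_gst")]]
List cpp_build_gst(IntegerVector tokens) {
    int n = tokens.size();
    if (n == 0) stop("empty token stream");
    std::vector<int> txt(n);
    for (int i = 0; i < n; ++i) txt[i] = tokens[i];

    STBuilder b(txt);
    b.build();
    int nn = (int) b.start_.size();

    std::vector<int> depth(nn, 0), firstPos(nn, -1);
    std::vector<int> leafLo(nn, 0), leafHi(nn, -1);
    std::vector<bool> isLeaf(nn, false);
    std::vector<int> leafSuffix;
    std::vector<int> eParent, eChild;
    leafSuffix.reserve(n);

    // iterative DFS; frame: (node, child iterator state) emulated with
    // explicit stacks of nodes and post flags
    std::vector<int> stack;
    std::vector< std::map<int,int>::const_iterator > its;
    stack.push_back(b.root);
    its.push_back(b.ch_[b.root].begin());
    depth[b.root] = 0;
    firstPos[b.root] = -1;
    leafLo[b.root] = 1;

    while (!stack.empty()) {
        int v = stack.back();
        if (its.back() == b.ch_[v].end()) {
            // post-visit
            if (b.ch_[v].empty()) {
                isLeaf[v] = true;
                leafSuffix.push_back(n - depth[v]); // 0-based suffix start
                leafLo[v] = (int) leafSuffix.size();
                leafHi[v] = (int) leafSuffix.size();
            } else {
                leafHi[v] = (int) leafSuffix.size();
            }
            stack.pop_back();
            its.pop_back();
        } else {
            int c = its.back()->second;
            ++its.back();
            eParent.push_back(v + 1);
            eChild.push_back(c + 1);
            int el = std::min(b.end_[c], n - 1) - b.start_[c] + 1;
            depth[c] = depth[v] + el;
            firstPos[c] = (v == b.root) ? b.start_[c] : firstPos[v];
            leafLo[c] = (int) leafSuffix.size() + 1;
            stack.push_back(c);
            its.push_back(b.ch_[c].begin());
        }
    }

    IntegerVector rStart(nn), rEnd(nn), rSlink(nn), rDepth(nn),
        rFirst(nn), rLo(nn), rHi(nn);
    LogicalVector rLeaf(nn);
    for (int v = 0; v < nn; ++v) {
        rStart[v] = (v == b.root) ? 0 : b.start_[v] + 1;
        int e = std::min(b.end_[v], n - 1);
        rEnd[v] = (v == b.root) ? 0 : e + 1;
        rSlink[v] = b.ch_[v].empty() ? 0
            : ((v == b.root) ? 0 : b.slink_[v] + 1);
        rLeaf[v] = b.ch_[v].empty();
        rDepth[v] = depth[v];
        rFirst[v] = firstPos[v] + 1; // root -> 0
        rLo[v] = leafLo[v];
        rHi[v] = leafHi[v];
    }
    IntegerVector rLeafSuffix(leafSuffix.size());
    for (size_t k = 0; k < leafSuffix.size(); ++k)
        rLeafSuffix[k] = leafSuffix[k] + 1;

    return List::create(
        _["nNodes"] = nn,
        _["root"] = b.root + 1,
        _["start"] = rStart,
        _["end"] = rEnd,
        _["slink"] = rSlink,
        _["isLeaf"] = rLeaf,
        _["tokenDepth"] = rDepth,
        _["firstPos"] = rFirst,
        _["leafLo"] = rLo,
        _["leafHi"] = rHi,
        _["leafSuffix"] = rLeafSuffix,
        _["edgeParent"] = wrap(eParent),
        _["edgeChild"] = wrap(eChild));
}
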