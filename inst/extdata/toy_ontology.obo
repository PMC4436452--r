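format-version: 1.2
ontology: synthetic molecular-function subset for examples and tests

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0000001
name: synthetic binding
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0000002
name: synthetic ion binding
namespace: molecular_function
is_a: GO:0000001 ! synthetic binding

[Term]
id: GO:0000003
name: synthetic zinc ion binding
namespace: molecular_function
is_a: GO:0000002 ! synthetic ion binding

[Term]
id: GO:0000009
name: synthetic catalytic activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function
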