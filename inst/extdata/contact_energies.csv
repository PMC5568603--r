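aa,A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y
A,-0.96,-1.067,-0.152,-0.152,-1.113,-0.625,-0.198,-1.372,-0.091,-1.265,-0.976,-0.152,-0.442,-0.152,0,-0.564,-0.579,-1.326,-0.549,-0.488
C,-1.067,-1.186,-0.169,-0.169,-1.236,-0.694,-0.22,-1.524,-0.102,-1.406,-1.084,-0.169,-0.491,-0.169,0,-0.627,-0.644,-1.474,-0.61,-0.542
D,-0.152,-0.169,-0.024,-0.024,-0.177,-0.099,-0.031,-0.218,-0.015,-0.201,-0.155,-0.024,-0.07,-0.024,0,-0.09,-0.092,-0.211,-0.087,-0.077
E,-0.152,-0.169,-0.024,-0.024,-0.177,-0.099,-0.031,-0.218,-0.015,-0.201,-0.155,-0.024,-0.07,-0.024,0,-0.09,-0.092,-0.211,-0.087,-0.077
F,-1.113,-1.236,-0.177,-0.177,-1.289,-0.724,-0.23,-1.59,-0.106,-1.466,-1.131,-0.177,-0.512,-0.177,0,-0.654,-0.671,-1.537,-0.636,-0.565
G,-0.625,-0.694,-0.099,-0.099,-0.724,-0.407,-0.129,-0.893,-0.06,-0.823,-0.635,-0.099,-0.288,-0.099,0,-0.367,-0.377,-0.863,-0.357,-0.317
H,-0.198,-0.22,-0.031,-0.031,-0.23,-0.129,-0.041,-0.283,-0.019,-0.261,-0.201,-0.031,-0.091,-0.031,0,-0.116,-0.12,-0.274,-0.113,-0.101
I,-1.372,-1.524,-0.218,-0.218,-1.59,-0.893,-0.283,-1.96,-0.131,-1.808,-1.394,-0.218,-0.632,-0.218,0,-0.806,-0.828,-1.895,-0.784,-0.697
K,-0.091,-0.102,-0.015,-0.015,-0.106,-0.06,-0.019,-0.131,-0.009,-0.121,-0.093,-0.015,-0.042,-0.015,0,-0.054,-0.055,-0.126,-0.052,-0.046
L,-1.265,-1.406,-0.201,-0.201,-1.466,-0.823,-0.261,-1.808,-0.121,-1.667,-1.285,-0.201,-0.582,-0.201,0,-0.743,-0.763,-1.747,-0.723,-0.643
M,-0.976,-1.084,-0.155,-0.155,-1.131,-0.635,-0.201,-1.394,-0.093,-1.285,-0.991,-0.155,-0.449,-0.155,0,-0.573,-0.588,-1.347,-0.558,-0.496
N,-0.152,-0.169,-0.024,-0.024,-0.177,-0.099,-0.031,-0.218,-0.015,-0.201,-0.155,-0.024,-0.07,-0.024,0,-0.09,-0.092,-0.211,-0.087,-0.077
P,-0.442,-0.491,-0.07,-0.07,-0.512,-0.288,-0.091,-0.632,-0.042,-0.582,-0.449,-0.07,-0.204,-0.07,0,-0.26,-0.267,-0.611,-0.253,-0.225
Q,-0.152,-0.169,-0.024,-0.024,-0.177,-0.099,-0.031,-0.218,-0.015,-0.201,-0.155,-0.024,-0.07,-0.024,0,-0.09,-0.092,-0.211,-0.087,-0.077
R,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
S,-0.564,-0.627,-0.09,-0.09,-0.654,-0.367,-0.116,-0.806,-0.054,-0.743,-0.573,-0.09,-0.26,-0.09,0,-0.331,-0.34,-0.779,-0.322,-0.286
T,-0.579,-0.644,-0.092,-0.092,-0.671,-0.377,-0.12,-0.828,-0.055,-0.763,-0.588,-0.092,-0.267,-0.092,0,-0.34,-0.349,-0.8,-0.331,-0.294
V,-1.326,-1.474,-0.211,-0.211,-1.537,-0.863,-0.274,-1.895,-0.126,-1.747,-1.347,-0.211,-0.611,-0.211,0,-0.779,-0.8,-1.832,-0.758,-0.674
W,-0.549,-0.61,-0.087,-0.087,-0.636,-0.357,-0.113,-0.784,-0.052,-0.723,-0.558,-0.087,-0.253,-0.087,0,-0.322,-0.331,-0.758,-0.314,-0.279
Y,-0.488,-0.542,-0.077,-0.077,-0.565,-0.317,-0.101,-0.697,-0.046,-0.643,-0.496,-0.077,-0.225,-0.077,0,-0.286,-0.294,-0.674,-0.279,-0.248
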